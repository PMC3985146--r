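# Synthetic genotype cohorts: the deterministic 93-subject fixture (FC93)
# and a seeded random-mating generator from haplotype frequencies.

fc93_spec <- function() {
  df <- read_tsv_data(vk_extdata("fc93_fixture.tsv"))
  df$count <- as.integer(df$count)
  df
}

#' The deterministic 93-subject fixture cohort (FC93)
#'
#' Expands the bundled fixture specification into a genotype cohort with
#' subject ids S001..S093. The joint genotypes are the unique assignment
#' compatible with the default haplotype matrix that reproduces the reference
#' cohort's haplotype-call counts (50 H1H1, 1 H1H2, 1 unique H1H7, 31
#' ambiguous H1H7-or-H1H9, 1 unique H1H9, 8 H7H7, 1 H8H9) and its published
#' 381/5808/9041 genotype marginals exactly; the 861 marginal is 92/0/1 (see
#' the package vignette for why the published 861 row cannot be matched
#' simultaneously).
#'
#' @return A genotype data.frame (`subject`, `snp381`..`snp9041`), 93 rows.
#' @export
#' @examples
#' table(fixture_cohort()$snp381)
fixture_cohort <- function() {
  spec <- fc93_spec()
  rows <- spec[rep(seq_len(nrow(spec)), spec$count), , drop = FALSE]
  out <- data.frame(subject = sprintf("S%03d", seq_len(nrow(rows))),
                    stringsAsFactors = FALSE)
  for (s in VK_SNP_IDS) {
    out[[paste0("snp", s)]] <- vapply(rows[[paste0("snp", s)]], function(p) {
      al <- split_pair(p); canonical_pair(al[1], al[2])
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

default_wildcard_fill <- function(matrix = vk_haplotype_matrix(),
                                  snps = vk_snp_sites()) {
  # default fill = the site's wild-type allele, per haplotype
  fills <- list()
  for (i in seq_len(nrow(matrix))) {
    pat <- matrix_alleles(matrix, matrix$name[i])
    wc <- names(pat)[pat == "*"]
    if (length(wc)) {
      fills[[matrix$name[i]]] <- setNames(
        vapply(wc, function(s) snps$wt_allele[snps$id == s], character(1)), wc)
    }
  }
  fills
}

instantiate_haplotype <- function(name, matrix, wildcard_fill) {
  pat <- matrix_alleles(matrix, name)
  wc <- names(pat)[pat == "*"]
  for (s in wc) {
    fill <- wildcard_fill[[name]][[s]]
    if (is.null(fill)) {
      stop(sprintf("configuration error: no wildcard fill for %s at SNP %s", name, s),
           call. = FALSE)
    }
    pat[[s]] <- fill
  }
  pat
}

#' Genotype generated by a haplotype pair
#'
#' The generator inverse of [infer_pairs()]: instantiates any wildcard sites
#' of the two patterns and returns the site-wise unordered allele pairs.
#'
#' @param hap_i,hap_j Haplotype names (e.g. `"H1"`).
#' @param wildcard_fill Named list, per haplotype, of named allele vectors
#'   for its wildcard sites; defaults to the wild-type allele at every
#'   wildcard.
#' @param matrix Haplotype definition matrix.
#' @return Named character vector of `"X/Y"` pairs over the four SNPs.
#' @export
#' @examples
#' genotypes_from_pair("H1", "H7")
genotypes_from_pair <- function(hap_i, hap_j,
                                wildcard_fill = default_wildcard_fill(matrix),
                                matrix = vk_haplotype_matrix()) {
  a <- instantiate_haplotype(hap_i, matrix, wildcard_fill)
  b <- instantiate_haplotype(hap_j, matrix, wildcard_fill)
  setNames(vapply(VK_SNP_IDS, function(s) canonical_pair(a[[s]], b[[s]]),
                  character(1)), VK_SNP_IDS)
}

#' Sample a random-mating cohort from haplotype frequencies
#'
#' Draws `2n` haplotypes independently with replacement (Hardy-Weinberg /
#' random mating), instantiates wildcard sites via `wildcard_fill`, and pairs
#' consecutive draws into `n` unphased genotypes. Fully reproducible for a
#' given seed.
#'
#' @param n Number of subjects.
#' @param hap_freqs Named numeric vector of haplotype frequencies summing
#'   to 1.
#' @param seed Integer seed.
#' @param wildcard_fill As in [genotypes_from_pair()].
#' @param matrix Haplotype definition matrix.
#' @return A genotype data.frame with attribute `"pairs"`: the generating
#'   haplotype pair per subject (canonical label, e.g. `"H1H7"`).
#' @export
#' @examples
#' sample_cohort(5, c(H1 = 0.7, H7 = 0.3), seed = 1)
sample_cohort <- function(n, hap_freqs, seed = 1L,
                          wildcard_fill = default_wildcard_fill(matrix),
                          matrix = vk_haplotype_matrix()) {
  stopifnot(n > 0)
  if (is.null(names(hap_freqs)) || !all(names(hap_freqs) %in% matrix$name)) {
    stop("configuration error: hap_freqs must be named by haplotypes in the matrix",
         call. = FALSE)
  }
  if (abs(sum(hap_freqs) - 1) > 1e-9 || any(hap_freqs < 0)) {
    stop("configuration error: frequencies must be non-negative and sum to 1",
         call. = FALSE)
  }
  draws <- with_seed(seed, sample(names(hap_freqs), 2 * n, replace = TRUE,
                                  prob = hap_freqs))
  hap_a <- draws[seq(1, 2 * n, by = 2)]
  hap_b <- draws[seq(2, 2 * n, by = 2)]

  # instantiate each distinct haplotype once
  inst <- lapply(setNames(unique(draws), unique(draws)),
                 instantiate_haplotype, matrix = matrix,
                 wildcard_fill = wildcard_fill)
  out <- data.frame(subject = sprintf("R%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (s in VK_SNP_IDS) {
    a <- vapply(inst, `[[`, character(1), s)[hap_a]
    b <- vapply(inst, `[[`, character(1), s)[hap_b]
    out[[paste0("snp", s)]] <- ifelse(a <= b, paste(a, b, sep = "/"),
                                      paste(b, a, sep = "/"))
  }
  attr(out, "pairs") <- ifelse(hap_a <= hap_b, paste0(hap_a, hap_b),
                               paste0(hap_b, hap_a))
  out
}
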