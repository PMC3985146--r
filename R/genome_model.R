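#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames
NULL

VK_SNP_IDS <- c("381", "861", "5808", "9041")

# Expected PCR2 band size per SNP (bp), from the assay design.
VK_BAND_SIZES <- c(`381` = 960L, `861` = 480L, `5808` = 280L, `9041` = 434L)

vk_extdata <- function(file) {
  path <- system.file("extdata", file, package = "vkhap", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (pkgload) inst/ may be on the search path directly
    path <- system.file("inst", "extdata", file, package = "vkhap", mustWork = TRUE)
  }
  path
}

read_tsv_data <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             colClasses = "character", check.names = FALSE)
}

#' The four VKORC1 SNP sites of the assay
#'
#' Returns the bundled SNP panel: site label, 1-based position on the
#' surrogate reference, the alternative published coordinate
#' (`hgvs_position`, always `position - 85`), and the plus-strand wild-type
#' and mutant alleles (381 C>T, 861 C>A, 5808 T>G, 9041 G>A).
#'
#' @return A data.frame with columns `id`, `position`, `hgvs_position`,
#'   `wt_allele`, `mut_allele`, one row per SNP in assay order.
#' @export
#' @examples
#' vk_snp_sites()
vk_snp_sites <- function() {
  df <- read_tsv_data(vk_extdata("snp_sites.tsv"))
  df$position <- as.integer(df$position)
  df$hgvs_position <- as.integer(df$hgvs_position)
  df
}

#' The nested multiplex primer panel
#'
#' Returns the bundled two-round primer panel. PCR1 rows are the outer common
#' pairs; PCR2 rows are the inner allele-specific primers (one wild-type and
#' one mutant variant per SNP, differing only at the 3'-terminal base) plus
#' their common partners. Footprints are 1-based inclusive plus-strand
#' coordinates; minus-strand primers are written 5'->3' and their planted
#' plus-strand slice is the reverse complement of `sequence`.
#'
#' @param round Optional filter, `"PCR1"` or `"PCR2"`.
#' @return A data.frame with one row per primer.
#' @export
#' @examples
#' subset(vk_primer_panel("PCR1"), select = c(name, sequence, footprint_start))
vk_primer_panel <- function(round = NULL) {
  df <- read_tsv_data(vk_extdata("primer_panel.tsv"))
  for (col in c("footprint_start", "footprint_end", "length"))
    df[[col]] <- as.integer(df[[col]])
  df$product_size <- suppressWarnings(as.integer(df$product_size))
  df$reported_tm <- as.numeric(df$reported_tm)
  df$snp_id[df$snp_id == "NA"] <- NA_character_
  if (!is.null(round)) {
    round <- match.arg(round, c("PCR1", "PCR2"))
    df <- df[df$round == round, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Default haplotype definition matrix
#'
#' The five VKORC1 haplotypes (H1, H2, H7, H8, H9) as allele patterns over
#' the four SNPs. `"*"` is a wildcard: the haplotyping decision tree never
#' consults that site for that haplotype, so it is left unconstrained (H1/H2
#' at 9041, H9 at 861). This is the minimal relaxation that reproduces the
#' observed ambiguous H1H7/H1H9 class together with unique H1H7, H1H9 and
#' H8H9 calls.
#'
#' @return A data.frame with columns `name`, `a381`, `a861`, `a5808`, `a9041`.
#' @export
#' @examples
#' vk_haplotype_matrix()
vk_haplotype_matrix <- function() {
  read_tsv_data(vk_extdata("haplotype_matrix.tsv"))
}

#' Assay protocol constants
#'
#' The optimized wet-lab protocol values carried as metadata: annealing
#' temperatures (PCR1 63.5 C, PCR2 64.8 C), 25 cycles, 200x inter-round
#' dilution, 20 uL reactions, and per-target primer concentrations.
#' These values are echoed into reports and logs; the amplification model is
#' presence/absence, so they do not alter simulation outcomes.
#'
#' @param max_product_bp Maximum amplicon size considered amplifiable (bp).
#' @param noise_700bp If `TRUE`, the simulator injects a nonspecific ~700 bp
#'   artifact band into the 381 lane (mimicking the DMSO-associated artifact);
#'   it never affects genotype calls.
#' @return A list of class `vk_protocol`.
#' @export
default_protocol <- function(max_product_bp = 2000L, noise_700bp = FALSE) {
  stopifnot(is.numeric(max_product_bp), length(max_product_bp) == 1)
  if (max_product_bp <= 0) stop("max_product_bp must be positive", call. = FALSE)
  structure(list(
    pcr1_annealing_c = 63.5,
    pcr2_annealing_c = 64.8,
    cycles = 25L,
    dilution_factor = 200L,
    reaction_volume_ul = 20L,
    primer_concentrations_um = list(
      PCR1 = c(`381&861` = 0.60, `5808` = 0.25, `9041` = 0.25),
      PCR2 = c(`381` = 0.70, `861` = 0.05, `5808` = 0.09, `9041` = 0.06)
    ),
    reagents = c(taq_buffer = "10X Taq buffer",
                 taq_polymerase = "5.0 U/uL Taq",
                 mgcl2 = "25 mM MgCl2",
                 dntp = "10 mM dNTP"),
    max_product_bp = as.integer(max_product_bp),
    noise_700bp = isTRUE(noise_700bp)
  ), class = "vk_protocol")
}

#' @export
print.vk_protocol <- function(x, ...) {
  cat("Nested multiplex PCR protocol (presence/absence model)\n")
  cat(sprintf("  annealing: PCR1 %.1f C, PCR2 %.1f C; %d cycles; %dx dilution; %d uL\n",
              x$pcr1_annealing_c, x$pcr2_annealing_c, x$cycles,
              x$dilution_factor, x$reaction_volume_ul))
  cat(sprintf("  max product size: %d bp; 700 bp artifact band: %s\n",
              x$max_product_bp, if (x$noise_700bp) "on" else "off"))
  invisible(x)
}

#' Reverse complement of a DNA sequence
#'
#' @param seq A single character string over the alphabet A, C, G, T, N.
#' @return The reverse complement, 5'->3'.
#' @export
#' @examples
#' reverse_complement("CGCCAACACCCCCCTTCA")
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (is.na(seq)) stop("sequence is NA", call. = FALSE)
  if (grepl("[^ACGTN]", seq)) {
    stop("invalid sequence: characters outside A/C/G/T/N", call. = FALSE)
  }
  if (!nzchar(seq)) return("")
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# The plus-strand slice a primer's footprint must carry (its own sequence for
# plus-strand primers, the reverse complement for minus-strand ones).
planted_slice <- function(primer) {
  if (primer$strand == "plus") primer$sequence else reverse_complement(primer$sequence)
}

# Binding core: the primer sequence with the allele-specific 3'-terminal base
# dropped. Common primers have no variable base, so the core is the full
# sequence. Used for uniqueness checks so WT and Mut variants are treated as
# one binding site.
primer_core <- function(primer) {
  if (primer$role == "common") return(primer$sequence)
  substr(primer$sequence, 1L, nchar(primer$sequence) - 1L)
}

count_occurrences <- function(pattern, subject_dna) {
  Biostrings::countPattern(pattern, subject_dna) +
    Biostrings::countPattern(reverse_complement(pattern), subject_dna)
}

# Unique footprints to plant: common + wt_specific rows, deduplicated by
# coordinates (PCR2 reuses two PCR1 common primers; mut variants share the
# wt footprint and differ only at the SNP base, which apply_alleles controls).
unique_footprints <- function(primers) {
  plant <- primers[primers$role != "mut_specific", , drop = FALSE]
  key <- paste(plant$footprint_start, plant$footprint_end, sep = "-")
  plant <- plant[!duplicated(key), , drop = FALSE]
  # mut rows must coincide with a planted footprint
  mut <- primers[primers$role == "mut_specific", , drop = FALSE]
  if (nrow(mut)) {
    mkey <- paste(mut$footprint_start, mut$footprint_end, sep = "-")
    if (!all(mkey %in% paste(plant$footprint_start, plant$footprint_end, sep = "-"))) {
      stop("configuration error: mutant-specific primer footprint has no wild-type counterpart",
           call. = FALSE)
    }
  }
  plant[order(plant$footprint_start), , drop = FALSE]
}

check_disjoint <- function(fp) {
  if (nrow(fp) < 2) return(invisible(TRUE))
  s <- fp$footprint_start; e <- fp$footprint_end
  o <- order(s)
  s <- s[o]; e <- e[o]
  if (any(s[-1] <= e[-length(e)])) {
    stop("configuration error: overlapping primer footprints", call. = FALSE)
  }
  invisible(TRUE)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build the surrogate reference sequence
#'
#' Constructs a synthetic reference of the requested length: every primer
#' footprint is planted verbatim at its published coordinate (minus-strand
#' primers as the reverse complement of their printed sequence), each SNP
#' position carries its wild-type allele, and all remaining positions are
#' filled with seeded pseudorandom bases. The filler is redrawn (bounded
#' retries) until every primer's binding core occurs exactly once on either
#' strand of both the all-wild-type and the all-mutant chromosome, so the
#' amplification model can never pick up stray binding sites.
#'
#' @param primers Primer panel data.frame (default [vk_primer_panel()]).
#' @param snps SNP table (default [vk_snp_sites()]).
#' @param seed Integer seed for the filler; the result is deterministic.
#' @param length Reference length in bp; must cover the largest footprint.
#' @param id Sequence name used in FASTA/VCF output.
#' @param max_retries Redraw attempts before giving up.
#' @return An object of class `vk_reference`: a list with `id`, `bases`
#'   (a single string, 1-based addressing), `snps`, and `primers`.
#' @export
#' @examples
#' ref <- build_reference(seed = 0)
#' substr(ref$bases, 257, 281)
build_reference <- function(primers = vk_primer_panel(), snps = vk_snp_sites(),
                            seed = 0L, length = 9500L,
                            id = "VKORC1_surrogate", max_retries = 25L) {
  stopifnot(nrow(primers) > 0, nrow(snps) > 0)
  if (length < max(primers$footprint_end)) {
    stop("configuration error: length shorter than the largest primer footprint",
         call. = FALSE)
  }
  fp <- unique_footprints(primers)
  check_disjoint(fp)

  fixed <- rep(FALSE, length)
  base_vec <- rep(NA_character_, length)
  for (i in seq_len(nrow(fp))) {
    idx <- fp$footprint_start[i]:fp$footprint_end[i]
    base_vec[idx] <- strsplit(planted_slice(fp[i, ]), "", fixed = TRUE)[[1]]
    fixed[idx] <- TRUE
  }
  # SNP positions carry the WT allele (all lie inside wt-specific footprints,
  # but enforce regardless)
  base_vec[snps$position] <- snps$wt_allele
  fixed[snps$position] <- TRUE

  cores <- vapply(seq_len(nrow(primers)), function(i) primer_core(primers[i, ]),
                  character(1))
  cores <- unique(cores)

  ok <- FALSE
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      filler <- sample(c("A", "C", "G", "T"), sum(!fixed), replace = TRUE)
      base_vec[!fixed] <- filler
      wt_chrom <- paste(base_vec, collapse = "")
      mut_vec <- base_vec
      mut_vec[snps$position] <- snps$mut_allele
      mut_chrom <- paste(mut_vec, collapse = "")
      wt_dna <- Biostrings::DNAString(wt_chrom)
      mut_dna <- Biostrings::DNAString(mut_chrom)
      counts_ok <- all(vapply(cores, function(p) {
        count_occurrences(p, wt_dna) == 1L && count_occurrences(p, mut_dna) == 1L
      }, logical(1)))
      if (counts_ok) { ok <- TRUE; break }
    }
  })
  if (!ok) {
    stop("generation error: could not make primer binding sites unique within retry budget",
         call. = FALSE)
  }
  structure(list(id = id, bases = paste(base_vec, collapse = ""),
                 snps = snps, primers = primers, seed = as.integer(seed)),
            class = "vk_reference")
}

#' @export
print.vk_reference <- function(x, ...) {
  cat(sprintf("Surrogate reference '%s': %d bp, %d SNPs, %d primer annotations (seed %d)\n",
              x$id, nchar(x$bases), nrow(x$snps), nrow(x$primers), x$seed))
  invisible(x)
}

#' Instantiate one chromosome from an allele assignment
#'
#' Overwrites the SNP positions of the reference with the assigned alleles and
#' returns the resulting chromosome sequence. Positions outside the SNP sites
#' are unchanged; every assigned base must be the site's wild-type or mutant
#' allele.
#'
#' @param ref A `vk_reference`.
#' @param assignment Named character vector, names are SNP ids ("381", ...),
#'   values single bases. Sites not named keep the wild-type allele.
#' @return A single character string (the chromosome).
#' @export
#' @examples
#' ref <- build_reference(seed = 0)
#' chrom <- apply_alleles(ref, c(`5808` = "G"))
#' substr(chrom, 5808, 5808)
apply_alleles <- function(ref, assignment = character()) {
  stopifnot(inherits(ref, "vk_reference"))
  bases <- ref$bases
  if (length(assignment) == 0) return(bases)
  if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
    stop("assignment must be a named vector of SNP alleles", call. = FALSE)
  }
  snps <- ref$snps
  for (id in names(assignment)) {
    row <- snps[snps$id == id, , drop = FALSE]
    if (nrow(row) != 1) stop(sprintf("unknown SNP id '%s'", id), call. = FALSE)
    allele <- assignment[[id]]
    if (!allele %in% c(row$wt_allele, row$mut_allele)) {
      stop(sprintf("invalid allele '%s' for SNP %s (expected %s or %s)",
                   allele, id, row$wt_allele, row$mut_allele), call. = FALSE)
    }
    substr(bases, row$position, row$position) <- allele
  }
  bases
}

#' Validate the primer annotations against a reference
#'
#' Checks, per primer: that the footprint slice of the reference matches the
#' primer (allele-specific primers are matched against the chromosome carrying
#' their designated allele), that the printed length equals the footprint
#' width, that the binding core occurs exactly once on either strand, and —
#' for allele-specific primers — that the 3'-terminal base (or its complement
#' for minus-strand primers) equals the designated allele.
#'
#' @param ref A `vk_reference`.
#' @param primers Primer panel (default: the panel stored in `ref`).
#' @param snps SNP table (default: stored in `ref`).
#' @return A data.frame of class `vk_validation` with one row per primer and
#'   logical check columns; attribute `pass` is `TRUE` only if every check
#'   passed.
#' @export
validate_annotations <- function(ref, primers = ref$primers, snps = ref$snps) {
  stopifnot(inherits(ref, "vk_reference"))
  wt_dna <- Biostrings::DNAString(ref$bases)
  n <- nrow(primers)
  out <- data.frame(
    name = primers$name, role = primers$role,
    length_match = logical(n), footprint_match = logical(n),
    unique_site = logical(n), anchor_match = NA,
    stringsAsFactors = FALSE
  )
  out$anchor_match <- rep(NA, n)
  for (i in seq_len(n)) {
    p <- primers[i, ]
    out$length_match[i] <- nchar(p$sequence) == p$length &&
      p$length == (p$footprint_end - p$footprint_start + 1L)

    # designated-allele chromosome for the footprint comparison
    bases <- ref$bases
    if (p$role == "mut_specific" && !is.na(p$snp_id)) {
      srow <- snps[snps$id == p$snp_id, ]
      substr(bases, srow$position, srow$position) <- srow$mut_allele
    }
    slice <- substr(bases, p$footprint_start, p$footprint_end)
    out$footprint_match[i] <- identical(slice, planted_slice(p))

    out$unique_site[i] <- count_occurrences(primer_core(p), wt_dna) == 1L

    if (p$role != "common" && !is.na(p$snp_id)) {
      srow <- snps[snps$id == p$snp_id, ]
      target <- if (p$role == "wt_specific") srow$wt_allele else srow$mut_allele
      three_prime <- substr(p$sequence, nchar(p$sequence), nchar(p$sequence))
      effective <- if (p$strand == "plus") three_prime else chartr("ACGT", "TGCA", three_prime)
      out$anchor_match[i] <- identical(effective, target)
    }
  }
  pass <- all(out$length_match) && all(out$footprint_match) &&
    all(out$unique_site) && all(out$anchor_match[!is.na(out$anchor_match)])
  structure(out, pass = pass, class = c("vk_validation", "data.frame"))
}

#' @export
print.vk_validation <- function(x, ...) {
  cat(sprintf("Primer annotation validation: %s\n",
              if (attr(x, "pass")) "PASS" else "FAIL"))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
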