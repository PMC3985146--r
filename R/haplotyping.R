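# Genotype calling from band patterns and diploid haplotype inference.
#
# The haplotyping decision tree over the four SNPs:
#   381 C -> (5808 T -> H1 ; 5808 G -> H2)
#   381 T -> (9041 G -> H9 ; 9041 A -> (861 C -> H7 ; 861 A -> H8))
# The pair-enumeration engine below is the diploid generalization: a
# haplotype pair is compatible with an unphased genotype iff at every site
# the genotype's unordered allele pair can be split between the two
# haplotype patterns (wildcards accept any allele).

NO_CALL <- "./."

canonical_pair <- function(a, b) {
  paste(sort(c(a, b)), collapse = "/")
}

split_pair <- function(x) strsplit(x, "/", fixed = TRUE)[[1]]

genotype_state <- function(pair, wt, mut) {
  if (identical(pair, NO_CALL)) return("no_call")
  al <- split_pair(pair)
  n_mut <- sum(al == mut)
  if (n_mut == 0) "hom_wt" else if (n_mut == 2) "hom_mut" else "het"
}

# Accept a genotype as a named character vector c(`381`="C/T", ...) or a
# one-row cohort data.frame (columns snp381..snp9041).
as_genotype_vec <- function(genotype) {
  if (is.data.frame(genotype)) {
    stopifnot(nrow(genotype) == 1)
    g <- setNames(as.character(genotype[1, paste0("snp", VK_SNP_IDS)]), VK_SNP_IDS)
    return(g)
  }
  nm <- names(genotype)
  nm <- sub("^snp", "", nm)
  g <- setNames(as.character(genotype), nm)
  if (!all(VK_SNP_IDS %in% names(g))) {
    stop("genotype must cover all four SNPs (381, 861, 5808, 9041)", call. = FALSE)
  }
  g[VK_SNP_IDS]
}

#' Call per-SNP genotypes from a tube band pattern
#'
#' Per SNP: band in the WT tube only -> homozygous wild type; bands in both
#' tubes -> heterozygous; Mut tube only -> homozygous mutant; neither ->
#' no-call (recorded, not an error).
#'
#' @param readout A `vk_assay_readout` from [simulate_assay()], or any list
#'   with named logical `wt_tube`/`mut_tube` over the four SNPs.
#' @param snps SNP table supplying the allele letters.
#' @return A one-row genotype data.frame (`subject`, `snp381`, `snp861`,
#'   `snp5808`, `snp9041`) with `"X/Y"` allele pairs or `"./."`.
#' @export
call_genotype_from_bands <- function(readout, snps = vk_snp_sites()) {
  wt_tube <- readout$wt_tube; mut_tube <- readout$mut_tube
  if (!all(VK_SNP_IDS %in% names(wt_tube)) || !all(VK_SNP_IDS %in% names(mut_tube))) {
    stop("readout must carry both tubes for all four SNPs", call. = FALSE)
  }
  calls <- vapply(VK_SNP_IDS, function(s) {
    row <- snps[snps$id == s, ]
    w <- isTRUE(wt_tube[[s]]); m <- isTRUE(mut_tube[[s]])
    if (w && !m) canonical_pair(row$wt_allele, row$wt_allele)
    else if (w && m) canonical_pair(row$wt_allele, row$mut_allele)
    else if (!w && m) canonical_pair(row$mut_allele, row$mut_allele)
    else NO_CALL
  }, character(1))
  out <- data.frame(subject = if (!is.null(readout$subject)) readout$subject else "subject1",
                    stringsAsFactors = FALSE)
  for (s in VK_SNP_IDS) out[[paste0("snp", s)]] <- calls[[s]]
  out
}

#' Classify one phased chromosome into a haplotype
#'
#' Applies the haplotyping decision tree to a concrete four-allele
#' assignment.
#'
#' @param phased_alleles Named character vector of single bases for the four
#'   SNPs.
#' @param snps SNP table (allele validation).
#' @return One of `"H1"`, `"H2"`, `"H7"`, `"H8"`, `"H9"`.
#' @export
#' @examples
#' classify_chromosome(c(`381` = "C", `861` = "C", `5808` = "T", `9041` = "G"))
classify_chromosome <- function(phased_alleles, snps = vk_snp_sites()) {
  a <- phased_alleles[VK_SNP_IDS]
  if (anyNA(a)) stop("all four alleles must be concrete", call. = FALSE)
  for (s in VK_SNP_IDS) {
    row <- snps[snps$id == s, ]
    if (!a[[s]] %in% c(row$wt_allele, row$mut_allele)) {
      stop(sprintf("invalid allele '%s' at SNP %s", a[[s]], s), call. = FALSE)
    }
  }
  if (a[["381"]] == "C") {
    if (a[["5808"]] == "T") "H1" else "H2"
  } else {
    if (a[["9041"]] == "G") "H9" else if (a[["861"]] == "C") "H7" else "H8"
  }
}

pattern_accepts <- function(pattern_allele, allele) {
  pattern_allele == "*" | pattern_allele == allele
}

matrix_alleles <- function(matrix_df, name) {
  row <- matrix_df[matrix_df$name == name, , drop = FALSE]
  if (nrow(row) != 1) stop(sprintf("unknown haplotype '%s'", name), call. = FALSE)
  setNames(as.character(row[1, paste0("a", VK_SNP_IDS)]), VK_SNP_IDS)
}

pair_compatible <- function(genotype, hap_i, hap_j) {
  for (s in VK_SNP_IDS) {
    al <- split_pair(genotype[[s]])
    ok <- (pattern_accepts(hap_i[[s]], al[1]) && pattern_accepts(hap_j[[s]], al[2])) ||
          (pattern_accepts(hap_i[[s]], al[2]) && pattern_accepts(hap_j[[s]], al[1]))
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Infer compatible haplotype pairs from an unphased genotype
#'
#' Enumerates all unordered haplotype pairs (including homozygous pairs) of
#' the definition matrix and keeps those compatible with the genotype at all
#' four sites. A genotype heterozygous at both 381 and 9041 (with 861 C/C,
#' 5808 T/T) is the assay's documented ambiguous class: both H1H7 and H1H9
#' remain compatible.
#'
#' @param genotype Named allele-pair vector or one-row genotype data.frame.
#' @param matrix Haplotype definition matrix (default
#'   [vk_haplotype_matrix()]).
#' @return An object of class `vk_haplotype_call`: `subject`,
#'   `compatible_pairs` (canonically sorted, e.g. `"H1H7"`), `status`
#'   (`unique`/`ambiguous`/`incompatible`/`undetermined`), `resolved_pair`
#'   (`NA` until [resolve_call()]), and `dose_class`.
#' @export
#' @examples
#' infer_pairs(c(`381` = "C/T", `861` = "C/C", `5808` = "T/T", `9041` = "A/G"))
infer_pairs <- function(genotype, matrix = vk_haplotype_matrix()) {
  if (nrow(matrix) == 0) stop("configuration error: empty haplotype matrix", call. = FALSE)
  subject <- if (is.data.frame(genotype) && "subject" %in% names(genotype))
    genotype$subject[1] else NA_character_
  g <- as_genotype_vec(genotype)

  if (any(g == NO_CALL)) {
    return(new_haplotype_call(subject, character(), "undetermined"))
  }
  names_h <- sort(matrix$name)
  pats <- lapply(setNames(names_h, names_h), function(n) matrix_alleles(matrix, n))
  compatible <- character()
  for (i in seq_along(names_h)) {
    for (j in i:length(names_h)) {
      if (pair_compatible(g, pats[[i]], pats[[j]])) {
        compatible <- c(compatible, paste0(names_h[i], names_h[j]))
      }
    }
  }
  status <- if (length(compatible) == 0) "incompatible"
            else if (length(compatible) == 1) "unique" else "ambiguous"
  new_haplotype_call(subject, compatible, status)
}

new_haplotype_call <- function(subject, compatible, status, resolved = NA_character_) {
  dose <- call_dose_class(compatible, resolved)
  structure(list(subject = subject, compatible_pairs = compatible,
                 status = status, resolved_pair = resolved, dose_class = dose),
            class = "vk_haplotype_call")
}

#' @export
print.vk_haplotype_call <- function(x, ...) {
  cat(sprintf("Haplotype call%s: {%s} [%s]",
              if (is.na(x$subject)) "" else paste0(" for ", x$subject),
              paste(x$compatible_pairs, collapse = ", "), x$status))
  if (!is.na(x$resolved_pair)) cat(" -> resolved", x$resolved_pair)
  cat(sprintf("; dose class: %s\n", x$dose_class))
  invisible(x)
}

#' Warfarin dose class of a haplotype pair
#'
#' H1 and H2 are the low-dose haplotypes; H7, H8 and H9 the high-dose ones.
#' A pair from one group is `low`/`high`; one of each is `mixed`.
#'
#' @param pair A pair label like `"H1H7"` or a character vector of two
#'   haplotype names.
#' @return `"low"`, `"mixed"` or `"high"`.
#' @export
#' @examples
#' dose_class("H1H7")
dose_class <- function(pair) {
  if (length(pair) == 1) {
    haps <- regmatches(pair, gregexpr("H[0-9]+", pair))[[1]]
  } else haps <- pair
  if (length(haps) != 2) stop("invalid-haplotype error: expected a pair", call. = FALSE)
  low <- c("H1", "H2"); high <- c("H7", "H8", "H9")
  if (!all(haps %in% c(low, high))) {
    stop(sprintf("invalid-haplotype error: unknown haplotype in '%s'",
                 paste(haps, collapse = "")), call. = FALSE)
  }
  if (all(haps %in% low)) "low" else if (all(haps %in% high)) "high" else "mixed"
}

call_dose_class <- function(compatible, resolved = NA_character_) {
  # pairs containing haplotypes outside the H1/H2 vs H7/H8/H9 grouping (a
  # user-extended matrix) have no dose class and yield "undetermined"
  safe_dose <- function(p) tryCatch(dose_class(p), error = function(e) NA_character_)
  if (!is.na(resolved)) {
    d <- safe_dose(resolved)
    return(if (is.na(d)) "undetermined" else d)
  }
  if (length(compatible) == 0) return("undetermined")
  classes <- unique(vapply(compatible, safe_dose, character(1)))
  if (length(classes) == 1 && !is.na(classes)) classes else "undetermined"
}

#' Resolve a haplotype call under an ambiguity policy
#'
#' `report_ambiguous` (default) resolves only unique calls. `assume_h1h7`
#' additionally resolves the exact `{H1H7, H1H9}` ambiguous class to H1H7 —
#' the simplification used when H1H9 is absent from the studied population;
#' other ambiguous sets stay unresolved.
#'
#' @param call A `vk_haplotype_call`.
#' @param policy `"report_ambiguous"` or `"assume_h1h7"`.
#' @return The call with `resolved_pair` (and `dose_class`) updated.
#' @export
resolve_call <- function(call, policy = c("report_ambiguous", "assume_h1h7")) {
  stopifnot(inherits(call, "vk_haplotype_call"))
  policy <- match.arg(policy)
  resolved <- call$resolved_pair
  if (call$status == "unique") {
    resolved <- call$compatible_pairs
  } else if (policy == "assume_h1h7" &&
             setequal(call$compatible_pairs, c("H1H7", "H1H9"))) {
    resolved <- "H1H7"
  }
  new_haplotype_call(call$subject, call$compatible_pairs, call$status, resolved)
}

#' Infer haplotype calls for a whole cohort
#'
#' Vectorized wrapper over [infer_pairs()] + [resolve_call()]; distinct
#' genotype combinations are inferred once and joined back.
#'
#' @param cohort Genotype data.frame (`subject`, `snp381`..`snp9041`).
#' @param matrix Haplotype definition matrix.
#' @param policy Ambiguity policy, see [resolve_call()].
#' @return A data.frame: `subject`, `compatible` (comma-separated),
#'   `status`, `resolved` (`NA` if unresolved), `dose_class`.
#' @export
#' @examples
#' infer_cohort(head(fixture_cohort()), policy = "assume_h1h7")
infer_cohort <- function(cohort, matrix = vk_haplotype_matrix(),
                         policy = c("report_ambiguous", "assume_h1h7")) {
  policy <- match.arg(policy)
  if (nrow(cohort) == 0) stop("empty-input error: no subjects", call. = FALSE)
  key <- do.call(paste, c(cohort[paste0("snp", VK_SNP_IDS)], sep = "|"))
  uniq <- !duplicated(key)
  lookup <- lapply(which(uniq), function(i) {
    resolve_call(infer_pairs(cohort[i, ], matrix), policy)
  })
  names(lookup) <- key[uniq]
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    cl <- lookup[[key[i]]]
    data.frame(subject = cohort$subject[i],
               compatible = paste(cl$compatible_pairs, collapse = ","),
               status = cl$status, resolved = cl$resolved_pair,
               dose_class = cl$dose_class, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
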