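# Cohort-level genotype/haplotype frequency tables and Hardy-Weinberg checks.

# Round half-up (not banker's rounding): frequency tables are formatted the
# way clinical genetics papers print them.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Per-SNP genotype count table
#'
#' Counts homozygous wild-type, heterozygous and homozygous mutant subjects
#' per SNP, with percentages of the cohort rounded half-up to 2 decimals.
#' Rows are in assay order (381, 861, 5808, 9041). Subjects with a no-call at
#' a site are tallied in `n_no_call` and excluded from the three genotype
#' classes at that site (percentages stay relative to the full cohort).
#'
#' @param cohort Genotype data.frame (`subject`, `snp381`..`snp9041`).
#' @param snps SNP table.
#' @return A data.frame of class `vk_site_counts` with columns `snp`,
#'   `n_hom_wt`, `n_het`, `n_hom_mut`, `n_no_call`, `pct_hom_wt`, `pct_het`,
#'   `pct_hom_mut`.
#' @export
#' @examples
#' genotype_table(fixture_cohort())
genotype_table <- function(cohort, snps = vk_snp_sites()) {
  if (is.null(cohort) || nrow(cohort) == 0) {
    stop("empty-input error: cohort has no subjects", call. = FALSE)
  }
  n <- nrow(cohort)
  rows <- lapply(VK_SNP_IDS, function(s) {
    srow <- snps[snps$id == s, ]
    states <- vapply(cohort[[paste0("snp", s)]], genotype_state,
                     character(1), wt = srow$wt_allele, mut = srow$mut_allele)
    cnt <- c(hom_wt = sum(states == "hom_wt"), het = sum(states == "het"),
             hom_mut = sum(states == "hom_mut"), no_call = sum(states == "no_call"))
    data.frame(snp = s,
               n_hom_wt = cnt[["hom_wt"]], n_het = cnt[["het"]],
               n_hom_mut = cnt[["hom_mut"]], n_no_call = cnt[["no_call"]],
               pct_hom_wt = round_half_up(100 * cnt[["hom_wt"]] / n),
               pct_het = round_half_up(100 * cnt[["het"]] / n),
               pct_hom_mut = round_half_up(100 * cnt[["hom_mut"]] / n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("vk_site_counts", "data.frame")
  out
}

#' Haplotype-pair frequency table
#'
#' Tabulates cohort haplotype calls. Resolved calls count under their pair
#' label; unresolved ambiguous calls form their own row labelled
#' `"X or Y"` (so under the `report_ambiguous` policy the assay's ambiguous
#' class appears as `"H1H7 or H1H9"`, while under `assume_h1h7` those
#' subjects count as H1H7). Incompatible/undetermined calls get their status
#' as label. Percentages are rounded half-up to 2 decimals.
#'
#' @param calls Either a cohort-call data.frame from [infer_cohort()] or a
#'   list of `vk_haplotype_call` objects.
#' @param policy If supplied, calls are re-resolved under this policy first.
#' @return A data.frame with columns `haplotype`, `n`, `pct`, sorted by
#'   label.
#' @export
#' @examples
#' haplotype_table(infer_cohort(fixture_cohort(), policy = "assume_h1h7"))
haplotype_table <- function(calls, policy = NULL) {
  if (inherits(calls, "vk_haplotype_call")) calls <- list(calls)
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, lapply(calls, function(cl) {
      if (!is.null(policy)) cl <- resolve_call(cl, policy)
      data.frame(subject = cl$subject,
                 compatible = paste(cl$compatible_pairs, collapse = ","),
                 status = cl$status, resolved = cl$resolved_pair,
                 dose_class = cl$dose_class, stringsAsFactors = FALSE)
    }))
  } else if (!is.null(policy)) {
    # re-resolve a cohort data.frame under the requested policy
    calls$resolved <- ifelse(
      calls$status == "unique", calls$compatible,
      ifelse(policy == "assume_h1h7" & calls$compatible %in% c("H1H7,H1H9"),
             "H1H7", NA_character_))
  }
  if (is.null(calls) || nrow(calls) == 0) {
    stop("empty-input error: no haplotype calls", call. = FALSE)
  }
  n <- nrow(calls)
  label <- ifelse(!is.na(calls$resolved), calls$resolved,
           ifelse(calls$status == "ambiguous",
                  gsub(",", " or ", calls$compatible, fixed = TRUE),
                  calls$status))
  cnt <- table(label)
  out <- data.frame(haplotype = names(cnt), n = as.integer(cnt),
                    pct = round_half_up(100 * as.integer(cnt) / n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_site_counts <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(nrow(counts) == 1)
    c(n_hom_wt = counts$n_hom_wt, n_het = counts$n_het, n_hom_mut = counts$n_hom_mut)
  } else {
    stopifnot(is.numeric(counts), length(counts) == 3)
    setNames(as.numeric(counts), c("n_hom_wt", "n_het", "n_hom_mut"))
  }
}

#' Allele frequencies by gene counting
#'
#' `q_mut = (2 * n_hom_mut + n_het) / (2n)`, and `p_wt = 1 - q_mut`.
#'
#' @param counts A one-row [genotype_table()] row or a numeric vector
#'   `c(hom_wt, het, hom_mut)`.
#' @return Named numeric vector `c(p_wt, q_mut)`.
#' @export
#' @examples
#' allele_frequencies(c(91, 0, 2))
allele_frequencies <- function(counts) {
  cnt <- as_site_counts(counts)
  n <- sum(cnt)
  if (n == 0) stop("empty-input error: zero subjects", call. = FALSE)
  q <- (2 * cnt[["n_hom_mut"]] + cnt[["n_het"]]) / (2 * n)
  c(p_wt = 1 - q, q_mut = q)
}

# Exact Hardy-Weinberg test: enumerate the conditional distribution of the
# heterozygote count given n and the minor-allele count, and sum the
# probabilities of all outcomes no more likely than the observed one.
hwe_exact_p <- function(n_hom_wt, n_het, n_hom_mut) {
  n <- n_hom_wt + n_het + n_hom_mut
  n_rare <- min(2 * n_hom_wt + n_het, 2 * n_hom_mut + n_het)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    rare_hom <- (n_rare - h) / 2
    common_hom <- n - h - rare_hom
    lgamma(n + 1) - lgamma(h + 1) - lgamma(rare_hom + 1) - lgamma(common_hom + 1) +
      h * log(2) + lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- which(hets == n_het)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Hardy-Weinberg equilibrium test for one SNP
#'
#' Computes allele frequencies by gene counting, the expected genotype
#' counts `(n p^2, 2 n p q, n q^2)`, and either a 1-df chi-square statistic
#' (no continuity correction; the default) or an exact test on the
#' heterozygote count (recommended when any expected cell is below 5, which
#' also sets `small_counts`). Monomorphic sites return a zero statistic and
#' p-value 1.
#'
#' @param counts A one-row [genotype_table()] row or numeric
#'   `c(hom_wt, het, hom_mut)`.
#' @param alpha Significance level for the `deviates` flag.
#' @param method `"chisq"` or `"exact"`.
#' @param snp Optional SNP label carried into the result.
#' @return A list of class `vk_hwe`: `snp`, `p_wt`, `q_mut`, `expected`,
#'   `chi_square`, `df`, `p_value`, `method`, `deviates`, `small_counts`.
#' @export
#' @examples
#' hwe_test(c(91, 0, 2))
hwe_test <- function(counts, alpha = 0.05, method = c("chisq", "exact"),
                     snp = NA_character_) {
  method <- match.arg(method)
  cnt <- as_site_counts(counts)
  if (is.data.frame(counts) && "snp" %in% names(counts)) snp <- counts$snp
  n <- sum(cnt)
  if (n == 0) stop("empty-input error: zero subjects", call. = FALSE)
  af <- allele_frequencies(cnt)
  p <- af[["p_wt"]]; q <- af[["q_mut"]]
  expected <- c(hom_wt = n * p^2, het = 2 * n * p * q, hom_mut = n * q^2)
  monomorphic <- p == 0 || q == 0
  if (monomorphic) {
    chi <- 0; pval <- 1
  } else if (method == "chisq") {
    obs <- c(cnt[["n_hom_wt"]], cnt[["n_het"]], cnt[["n_hom_mut"]])
    chi <- sum((obs - expected)^2 / expected)
    pval <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  } else {
    obs <- c(cnt[["n_hom_wt"]], cnt[["n_het"]], cnt[["n_hom_mut"]])
    chi <- sum((obs - expected)^2 / expected)
    pval <- hwe_exact_p(cnt[["n_hom_wt"]], cnt[["n_het"]], cnt[["n_hom_mut"]])
  }
  structure(list(snp = snp, p_wt = p, q_mut = q, expected = expected,
                 chi_square = chi, df = 1L, p_value = pval, method = method,
                 alpha = alpha, deviates = pval < alpha,
                 small_counts = !monomorphic && any(expected < 5)),
            class = "vk_hwe")
}

#' @export
print.vk_hwe <- function(x, ...) {
  cat(sprintf("HWE %s test%s: p_wt=%.4f q_mut=%.4f chi2=%.3f (df=1) p=%.4g%s\n",
              x$method, if (is.na(x$snp)) "" else paste0(" [SNP ", x$snp, "]"),
              x$p_wt, x$q_mut, x$chi_square, x$p_value,
              if (x$deviates) " *deviates*" else ""))
  cat(sprintf("  expected counts: hom_wt=%.2f het=%.2f hom_mut=%.2f%s\n",
              x$expected[["hom_wt"]], x$expected[["het"]], x$expected[["hom_mut"]],
              if (x$small_counts) "  [small expected cells]" else ""))
  invisible(x)
}

#' HWE screen over a whole genotype table
#'
#' @param site_counts Output of [genotype_table()].
#' @param ... Passed to [hwe_test()].
#' @return A data.frame with one row per SNP.
#' @export
hwe_screen <- function(site_counts, ...) {
  rows <- lapply(seq_len(nrow(site_counts)), function(i) {
    h <- hwe_test(site_counts[i, ], ...)
    data.frame(snp = h$snp, p_wt = h$p_wt, q_mut = h$q_mut,
               chi_square = h$chi_square, p_value = h$p_value,
               deviates = h$deviates, small_counts = h$small_counts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
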