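# Two-round nested allele-specific multiplex PCR as a deterministic
# presence/absence amplification model. A primer extends only from a site
# where it matches the template full-length AND at its 3'-terminal base;
# the single 3' mismatch engineered into the allele-specific primers is the
# whole discrimination mechanism.

#' Find primer binding sites on a template
#'
#' Scans both strands for placements where the primer aligns with at most
#' `max_internal_mismatches` mismatches outside its 3'-terminal base.
#' Whether the 3'-terminal base itself pairs is recorded separately in
#' `three_prime_match`; `full_match` means no mismatch anywhere. Coordinates
#' are 1-based inclusive on the template's plus strand; for minus-strand
#' sites the primer's 3' end sits at `start`.
#'
#' @param template A single character string (DNA).
#' @param primer One primer: a one-row data.frame or list with at least
#'   `name` and `sequence`.
#' @param max_internal_mismatches Allowed mismatches outside the 3' base.
#' @return A data.frame with columns `primer`, `strand`, `start`, `end`,
#'   `full_match`, `three_prime_match`, sorted by (strand, start). Zero rows
#'   if the primer has no site.
#' @export
find_binding_sites <- function(template, primer, max_internal_mismatches = 0L) {
  stopifnot(is.character(template), length(template) == 1, nzchar(template))
  pseq <- primer$sequence
  pname <- if (!is.null(primer$name)) primer$name else pseq
  k <- nchar(pseq)
  subject <- Biostrings::DNAString(template)

  scan_strand <- function(pattern, strand) {
    hits <- Biostrings::matchPattern(pattern, subject,
                                     max.mismatch = max_internal_mismatches + 1L)
    st <- BiocGenerics::start(hits); en <- BiocGenerics::end(hits)
    keep <- st >= 1L & en <= nchar(template)
    st <- st[keep]; en <- en[keep]
    if (!length(st)) return(NULL)
    pat_chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
    rows <- lapply(seq_along(st), function(j) {
      tmpl_chars <- strsplit(substr(template, st[j], en[j]), "", fixed = TRUE)[[1]]
      mism <- which(tmpl_chars != pat_chars)
      # the primer's 3' end maps to the last slice base on plus, first on minus
      three_idx <- if (strand == "plus") k else 1L
      internal <- setdiff(mism, three_idx)
      if (length(internal) > max_internal_mismatches) return(NULL)
      data.frame(primer = pname, strand = strand, start = st[j], end = en[j],
                 full_match = length(mism) == 0L,
                 three_prime_match = !(three_idx %in% mism),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  out <- rbind(scan_strand(pseq, "plus"),
               scan_strand(reverse_complement(pseq), "minus"))
  if (is.null(out)) {
    out <- data.frame(primer = character(), strand = character(),
                      start = integer(), end = integer(),
                      full_match = logical(), three_prime_match = logical(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_amplicons <- function() {
  data.frame(template = character(), fwd_primer = character(),
             rev_primer = character(), start = integer(), end = integer(),
             size = integer(), sequence = character(),
             stringsAsFactors = FALSE)
}

#' Simulate one PCR round on a set of templates
#'
#' For every template and every pair (plus-strand site of primer A,
#' minus-strand site of primer B) with A's 3' end strictly upstream of B's
#' 3' end, product size at most `max_product_bp`, and both sites matching
#' full-length including the 3' base, emits one amplicon spanning
#' `A.start..B.end`. Identical (sequence, primer pair) products arising from
#' identical templates are deduplicated; output is ordered by size, then
#' primer names.
#'
#' @param templates Character vector of template sequences; names (if any)
#'   become template ids.
#' @param primer_mix Primer panel data.frame (rows are the primers in the
#'   tube).
#' @param max_product_bp Largest product considered amplifiable.
#' @param max_internal_mismatches Passed to [find_binding_sites()].
#' @return An amplicon data.frame: `template`, `fwd_primer`, `rev_primer`,
#'   `start`, `end`, `size`, `sequence`.
#' @export
#' @examples
#' ref <- build_reference(seed = 0)
#' amp <- simulate_round(apply_alleles(ref), vk_primer_panel("PCR1"))
#' amp$size
simulate_round <- function(templates, primer_mix, max_product_bp = 2000L,
                           max_internal_mismatches = 0L) {
  if (nrow(primer_mix) == 0) stop("configuration error: empty primer mix", call. = FALSE)
  if (max_product_bp <= 0) stop("configuration error: max_product_bp must be positive", call. = FALSE)
  if (length(templates) == 0) return(empty_amplicons())
  ids <- names(templates)
  if (is.null(ids)) ids <- paste0("template", seq_along(templates))

  res <- list()
  for (t in seq_along(templates)) {
    tmpl <- templates[[t]]
    sites <- do.call(rbind, lapply(seq_len(nrow(primer_mix)), function(i) {
      find_binding_sites(tmpl, primer_mix[i, ], max_internal_mismatches)
    }))
    if (is.null(sites) || !nrow(sites)) next
    extendable <- sites[sites$full_match & sites$three_prime_match, , drop = FALSE]
    fwd <- extendable[extendable$strand == "plus", , drop = FALSE]
    rev_ <- extendable[extendable$strand == "minus", , drop = FALSE]
    if (!nrow(fwd) || !nrow(rev_)) next
    for (i in seq_len(nrow(fwd))) {
      for (j in seq_len(nrow(rev_))) {
        if (fwd$end[i] >= rev_$start[j]) next      # A's 3' end must lie upstream of B's
        size <- rev_$end[j] - fwd$start[i] + 1L
        if (size > max_product_bp) next
        res[[length(res) + 1L]] <- data.frame(
          template = ids[t], fwd_primer = fwd$primer[i], rev_primer = rev_$primer[j],
          start = fwd$start[i], end = rev_$end[j], size = size,
          sequence = substr(tmpl, fwd$start[i], rev_$end[j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty_amplicons())
  out <- do.call(rbind, res)
  out <- out[!duplicated(out[, c("sequence", "fwd_primer", "rev_primer")]), , drop = FALSE]
  out <- out[order(out$size, out$fwd_primer, out$rev_primer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# PCR2 tube mixes: the allele-specific primers of one class plus their common
# partners.
pcr2_mix <- function(primers, class = c("wt", "mut")) {
  class <- match.arg(class)
  p2 <- primers[primers$round == "PCR2", , drop = FALSE]
  keep <- p2$role == "common" | p2$role == paste0(class, "_specific")
  p2[keep, , drop = FALSE]
}

as_diplotype <- function(diplotype, snps) {
  if (is.matrix(diplotype)) diplotype <- list(diplotype[1, ], diplotype[2, ])
  if (!is.list(diplotype) || length(diplotype) != 2) {
    stop("invalid-diplotype error: expected two allele assignments", call. = FALSE)
  }
  lapply(diplotype, function(h) {
    if (is.null(names(h)) || !all(snps$id %in% names(h))) {
      stop("invalid-diplotype error: each chromosome must assign all four SNPs",
           call. = FALSE)
    }
    h[snps$id]
  })
}

#' Simulate the full two-round assay for one subject
#'
#' Instantiates the two chromosome sequences of a diplotype, runs the PCR1
#' multiplex on both, pools the products (the 200x dilution between rounds is
#' logged bookkeeping only), then runs PCR2 twice on the pooled amplicons:
#' once with the four wild-type-specific primers plus their common partners
#' (the WT tube) and once with the mutant-specific set (the Mut tube). A band
#' is called present for a SNP only if an amplicon of exactly the expected
#' size (381: 960 bp, 861: 480 bp, 5808: 280 bp, 9041: 434 bp) exists in that
#' tube.
#'
#' @param diplotype A list of two named allele vectors (names "381", "861",
#'   "5808", "9041"), or a 2-row matrix with those column names.
#' @param ref A `vk_reference`.
#' @param protocol A `vk_protocol` ([default_protocol()]).
#' @param subject Subject id carried into the readout.
#' @return An object of class `vk_assay_readout`: PCR1/PCR2 amplicon tables,
#'   `wt_tube`/`mut_tube` presence maps, `band_sizes`, and any artifact bands.
#' @export
#' @examples
#' ref <- build_reference(seed = 0)
#' wt <- setNames(vk_snp_sites()$wt_allele, vk_snp_sites()$id)
#' simulate_assay(list(wt, wt), ref)
simulate_assay <- function(diplotype, ref, protocol = default_protocol(),
                           subject = "subject1") {
  stopifnot(inherits(ref, "vk_reference"), inherits(protocol, "vk_protocol"))
  diplotype <- as_diplotype(diplotype, ref$snps)
  chroms <- c(chromA = apply_alleles(ref, diplotype[[1]]),
              chromB = apply_alleles(ref, diplotype[[2]]))

  pcr1 <- simulate_round(chroms, ref$primers[ref$primers$round == "PCR1", ],
                         protocol$max_product_bp)
  # 200x dilution between rounds: bookkeeping only in this model
  templates2 <- setNames(pcr1$sequence,
                         paste0("pcr1_", seq_len(nrow(pcr1)), "_", pcr1$size, "bp"))
  wt_products <- simulate_round(templates2, pcr2_mix(ref$primers, "wt"),
                                protocol$max_product_bp)
  mut_products <- simulate_round(templates2, pcr2_mix(ref$primers, "mut"),
                                 protocol$max_product_bp)

  presence <- function(products) {
    vapply(VK_SNP_IDS, function(s) any(products$size == VK_BAND_SIZES[[s]]),
           logical(1))
  }
  artifacts <- empty_amplicons()
  if (isTRUE(protocol$noise_700bp)) {
    # DMSO-associated nonspecific band near 700 bp in the 381 lane; cosmetic
    artifacts <- data.frame(template = "artifact", fwd_primer = "nonspecific",
                            rev_primer = "nonspecific", start = NA_integer_,
                            end = NA_integer_, size = 700L,
                            sequence = NA_character_, stringsAsFactors = FALSE)
  }
  structure(list(subject = subject,
                 pcr1_bands = pcr1,
                 wt_products = wt_products,
                 mut_products = mut_products,
                 wt_tube = presence(wt_products),
                 mut_tube = presence(mut_products),
                 band_sizes = VK_BAND_SIZES,
                 artifacts = artifacts,
                 protocol = protocol),
            class = "vk_assay_readout")
}

#' @export
print.vk_assay_readout <- function(x, ...) {
  cat(sprintf("Assay readout for %s\n", x$subject))
  cat(sprintf("  PCR1 products: %s bp\n",
              paste(sort(unique(x$pcr1_bands$size), decreasing = TRUE), collapse = ", ")))
  tab <- data.frame(snp = VK_SNP_IDS, expected_bp = unname(x$band_sizes),
                    wt_tube = unname(x$wt_tube), mut_tube = unname(x$mut_tube))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Render virtual gel lanes as text
#'
#' Draws bands against a 100 bp ladder on a log-size scale, largest sizes at
#' the top, one column per lane. Output is deterministic, suitable for
#' golden-file comparison. An empty lane is a negative control.
#'
#' @param lanes A named list of integer band-size vectors, or a single
#'   amplicon data.frame (one lane named "lane1").
#' @param ladder_step_bp Ladder rung spacing in bp.
#' @return A character vector of lines (also printed class `vk_gel`).
#' @export
#' @examples
#' render_gel(list(PCR1 = c(1060L, 398L, 853L), neg = integer()))
render_gel <- function(lanes, ladder_step_bp = 100L) {
  if (is.data.frame(lanes)) lanes <- list(lane1 = lanes$size)
  stopifnot(is.list(lanes))
  sizes <- unlist(lanes, use.names = FALSE)
  if (any(sizes <= 0)) stop("band sizes must be positive", call. = FALSE)
  top <- max(c(sizes, 1000L))
  top <- as.integer(ceiling(top / ladder_step_bp) * ladder_step_bp)
  rungs <- seq(top, ladder_step_bp, by = -ladder_step_bp)
  marks <- sort(unique(c(rungs, sizes)), decreasing = TRUE)

  lane_names <- names(lanes)
  if (is.null(lane_names)) lane_names <- paste0("lane", seq_along(lanes))
  width <- max(nchar(lane_names), 6L)
  header <- paste0(formatC("bp", width = 6), " ladder ",
                   paste(formatC(lane_names, width = width), collapse = " "))
  lines <- vapply(marks, function(m) {
    rung <- if (m %in% rungs) "--" else "  "
    cells <- vapply(lanes, function(b) {
      formatC(if (m %in% b) "====" else "", width = width)
    }, character(1))
    paste0(formatC(m, width = 6), "   ", rung, "   ", paste(cells, collapse = " "))
  }, character(1))
  structure(c(header, lines), class = "vk_gel")
}

#' @export
print.vk_gel <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
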