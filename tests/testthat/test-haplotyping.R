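# Band-pattern genotype calls, the haplotyping tree, and pair enumeration.

test_that("call_genotype_from_bands maps tube patterns to genotype states", {
  mk <- function(wt, mut) list(subject = "S", wt_tube = wt, mut_tube = mut)
  all_true <- setNames(rep(TRUE, 4), c("381", "861", "5808", "9041"))
  all_false <- setNames(rep(FALSE, 4), c("381", "861", "5808", "9041"))

  g <- call_genotype_from_bands(mk(all_true, all_false))
  expect_identical(unlist(g[1, -1], use.names = FALSE),
                   c("C/C", "C/C", "T/T", "G/G"))

  both381 <- all_false; both381[["381"]] <- TRUE
  g <- call_genotype_from_bands(mk(all_true, both381))
  expect_identical(g$snp381, "C/T")

  none861 <- all_true; none861[["861"]] <- FALSE
  g <- call_genotype_from_bands(mk(none861, all_false))
  expect_identical(g$snp861, "./.")

  g <- call_genotype_from_bands(mk(all_false, all_true))
  expect_identical(unlist(g[1, -1], use.names = FALSE),
                   c("T/T", "A/A", "G/G", "A/A"))
})

test_that("classify_chromosome follows the decision tree", {
  cc <- function(a381, a861, a5808, a9041) {
    classify_chromosome(c(`381` = a381, `861` = a861, `5808` = a5808,
                          `9041` = a9041))
  }
  expect_identical(cc("C", "C", "T", "G"), "H1")
  expect_identical(cc("C", "C", "G", "G"), "H2")
  expect_identical(cc("T", "C", "T", "G"), "H9")
  expect_identical(cc("T", "C", "T", "A"), "H7")
  expect_identical(cc("T", "A", "T", "A"), "H8")
  expect_error(cc("G", "C", "T", "A"), "invalid allele")
})

test_that("infer_pairs reproduces the documented calls", {
  ambiguous <- infer_pairs(c(`381` = "C/T", `861` = "C/C", `5808` = "T/T",
                             `9041` = "A/G"))
  expect_setequal(ambiguous$compatible_pairs, c("H1H7", "H1H9"))
  expect_identical(ambiguous$status, "ambiguous")
  expect_identical(ambiguous$dose_class, "mixed")

  h7h8 <- infer_pairs(c(`381` = "T/T", `861` = "A/C", `5808` = "T/T",
                        `9041` = "A/A"))
  expect_identical(h7h8$compatible_pairs, "H7H8")
  expect_identical(h7h8$status, "unique")

  h1h1 <- infer_pairs(c(`381` = "C/C", `861` = "C/C", `5808` = "T/T",
                        `9041` = "G/G"))
  expect_identical(h1h1$compatible_pairs, "H1H1")

  none <- infer_pairs(c(`381` = "C/C", `861` = "A/A", `5808` = "T/T",
                        `9041` = "G/G"))
  expect_identical(none$status, "incompatible")
  expect_identical(none$compatible_pairs, character())
  expect_identical(none$dose_class, "undetermined")

  nc <- infer_pairs(c(`381` = "C/C", `861` = "./.", `5808` = "T/T",
                      `9041` = "G/G"))
  expect_identical(nc$status, "undetermined")

  expect_error(infer_pairs(c(`381` = "C/C", `861` = "C/C", `5808` = "T/T",
                             `9041` = "G/G"), matrix = vk_haplotype_matrix()[0, ]),
               "empty haplotype matrix")
})

test_that("infer_pairs is invariant to within-site allele order", {
  g1 <- infer_pairs(c(`381` = "C/T", `861` = "C/C", `5808` = "T/T", `9041` = "A/G"))
  g2 <- infer_pairs(c(`381` = "T/C", `861` = "C/C", `5808` = "T/T", `9041` = "G/A"))
  expect_identical(g1$compatible_pairs, g2$compatible_pairs)
})

test_that("resolve_call applies the ambiguity policies", {
  amb <- infer_pairs(c(`381` = "C/T", `861` = "C/C", `5808` = "T/T", `9041` = "A/G"))
  r <- resolve_call(amb, "assume_h1h7")
  expect_identical(r$resolved_pair, "H1H7")
  expect_identical(r$dose_class, "mixed")
  r <- resolve_call(amb, "report_ambiguous")
  expect_true(is.na(r$resolved_pair))

  uni <- infer_pairs(c(`381` = "C/C", `861` = "C/C", `5808` = "T/T", `9041` = "G/G"))
  expect_identical(resolve_call(uni, "report_ambiguous")$resolved_pair, "H1H1")
  expect_identical(resolve_call(uni, "assume_h1h7")$resolved_pair, "H1H1")

  none <- infer_pairs(c(`381` = "C/C", `861` = "A/A", `5808` = "T/T", `9041` = "G/G"))
  expect_true(is.na(resolve_call(none, "assume_h1h7")$resolved_pair))
  expect_error(resolve_call(amb, "drop_ambiguous"), "arg")
})

test_that("dose_class groups haplotypes by warfarin dose requirement", {
  expect_identical(dose_class("H1H1"), "low")
  expect_identical(dose_class("H1H2"), "low")
  expect_identical(dose_class("H7H7"), "high")
  expect_identical(dose_class("H8H9"), "high")
  expect_identical(dose_class("H1H7"), "mixed")
  expect_identical(dose_class(c("H2", "H9")), "mixed")
  expect_error(dose_class("H1H3"), "invalid-haplotype")
})

test_that("tree and pair enumeration agree on every fully concrete unique call", {
  grid <- all_genotypes()
  matrix_df <- vk_haplotype_matrix()
  concrete <- c("H7", "H8")  # wildcard-free patterns
  checked <- 0L
  for (i in seq_len(nrow(grid))) {
    g <- setNames(as.character(grid[i, ]), names(grid))
    call <- infer_pairs(g, matrix_df)
    phasings <- list()
    het <- vapply(g, function(p) {
      al <- strsplit(p, "/", fixed = TRUE)[[1]]; al[1] != al[2]
    }, logical(1))
    # enumerate every phasing; collect the tree's verdict per phasing
    combos <- if (sum(het) == 0) data.frame(.none = FALSE)
              else expand.grid(rep(list(c(FALSE, TRUE)), sum(het)))
    tree_pairs <- unique(vapply(seq_len(nrow(combos)), function(r) {
      a <- character(); b <- character()
      flip <- unlist(combos[r, ]); k <- 0L
      for (s in names(g)) {
        al <- strsplit(g[[s]], "/", fixed = TRUE)[[1]]
        if (het[[s]]) { k <- k + 1L; if (flip[k]) al <- rev(al) }
        a[[s]] <- al[1]; b[[s]] <- al[2]
      }
      paste(sort(c(classify_chromosome(a), classify_chromosome(b))), collapse = "")
    }, character(1)))
    if (call$status == "unique" &&
        all(strsplit(call$compatible_pairs, "(?<=.)(?=H)", perl = TRUE)[[1]] %in% concrete)) {
      expect_true(call$compatible_pairs %in% tree_pairs)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 3L)  # H7H7, H7H8, H8H8 genotypes all occur in the grid
})

test_that("generation from any pair is recovered by inference (round trip)", {
  matrix_df <- vk_haplotype_matrix()
  snps <- vk_snps()
  haps <- matrix_df$name
  fills_for <- function(name) {
    pat <- matrix_df[matrix_df$name == name, paste0("a", snps$id)]
    wc <- snps$id[as.character(pat) == "*"]
    if (!length(wc)) return(list(setNames(character(), character())))
    opts <- lapply(wc, function(s) c(snps$wt_allele[snps$id == s],
                                     snps$mut_allele[snps$id == s]))
    grid <- expand.grid(opts, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(grid)), function(r) setNames(as.character(grid[r, ]), wc))
  }
  inst <- function(name, fill) {
    pat <- setNames(as.character(matrix_df[matrix_df$name == name, paste0("a", snps$id)]),
                    snps$id)
    for (s in names(fill)) pat[[s]] <- fill[[s]]
    pat
  }
  for (i in seq_along(haps)) for (j in i:length(haps)) {
    for (fa in fills_for(haps[i])) for (fb in fills_for(haps[j])) {
      a <- inst(haps[i], fa); b <- inst(haps[j], fb)
      g <- setNames(vapply(snps$id, function(s)
        paste(sort(c(a[[s]], b[[s]])), collapse = "/"), character(1)), snps$id)
      call <- infer_pairs(g, matrix_df)
      expect_true(paste0(haps[i], haps[j]) %in% call$compatible_pairs,
                  label = sprintf("%s%s with fills recovered", haps[i], haps[j]))
    }
  }
})

test_that("adding a haplotype pattern never shrinks any compatible set", {
  grid <- all_genotypes()
  base <- vk_haplotype_matrix()
  extended <- rbind(base, data.frame(name = "HX", a381 = "*", a861 = "*",
                                     a5808 = "*", a9041 = "*"))
  for (i in seq_len(nrow(grid))) {
    g <- setNames(as.character(grid[i, ]), names(grid))
    before <- infer_pairs(g, base)$compatible_pairs
    after <- infer_pairs(g, extended)$compatible_pairs
    expect_true(all(before %in% after))
  }
})

test_that("infer_cohort joins per-genotype calls back to subjects", {
  fc <- fixture_cohort()
  calls <- infer_cohort(fc, policy = "assume_h1h7")
  expect_identical(nrow(calls), 93L)
  expect_identical(sum(calls$resolved == "H1H7", na.rm = TRUE), 32L)
  expect_identical(calls$subject, fc$subject)
  expect_error(infer_cohort(fc[0, ]), "no subjects")
})
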