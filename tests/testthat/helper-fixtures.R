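# Shared fixtures, built once per test run.

.vk_cache <- new.env(parent = emptyenv())

# Surrogate reference, seed 0 / 9500 bp (the default study conditions).
vk_test_ref <- function() {
  if (is.null(.vk_cache$ref)) .vk_cache$ref <- build_reference(seed = 0, length = 9500)
  .vk_cache$ref
}

vk_snps <- function() {
  if (is.null(.vk_cache$snps)) .vk_cache$snps <- vk_snp_sites()
  .vk_cache$snps
}

wt_assignment <- function() {
  s <- vk_snps()
  setNames(s$wt_allele, s$id)
}

mut_assignment <- function() {
  s <- vk_snps()
  setNames(s$mut_allele, s$id)
}

# Split a canonical unphased genotype ("X/Y" per site) into one phasing:
# first allele -> chromosome A, second -> chromosome B.
diplotype_from_genotype <- function(g) {
  a <- vapply(g, function(p) strsplit(p, "/", fixed = TRUE)[[1]][1], character(1))
  b <- vapply(g, function(p) strsplit(p, "/", fixed = TRUE)[[1]][2], character(1))
  list(a, b)
}

# All 81 unphased genotypes over the four SNPs (per site: hom-wt, het,
# hom-mut), as canonical "X/Y" vectors.
all_genotypes <- function() {
  s <- vk_snps()
  per_site <- lapply(seq_len(nrow(s)), function(i) {
    al <- sort(c(s$wt_allele[i], s$mut_allele[i]))
    c(paste(s$wt_allele[i], s$wt_allele[i], sep = "/"),
      paste(al[1], al[2], sep = "/"),
      paste(s$mut_allele[i], s$mut_allele[i], sep = "/"))
  })
  grid <- expand.grid(per_site, stringsAsFactors = FALSE)
  names(grid) <- s$id
  grid
}

# Brute-force band-presence oracle: a tube's allele-specific primer extends
# iff at least one chromosome carries the tube's allele at that SNP.
oracle_tubes <- function(diplotype) {
  s <- vk_snps()
  wt <- vapply(s$id, function(id) {
    s$wt_allele[s$id == id] %in% c(diplotype[[1]][[id]], diplotype[[2]][[id]])
  }, logical(1))
  mut <- vapply(s$id, function(id) {
    s$mut_allele[s$id == id] %in% c(diplotype[[1]][[id]], diplotype[[2]][[id]])
  }, logical(1))
  list(wt_tube = wt, mut_tube = mut)
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
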