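Package: vkhap
Title: Nested Allele-Specific Multiplex PCR Simulation and VKORC1 Haplotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico model of a two-round nested allele-specific multiplex
    PCR assay for the four VKORC1 warfarin-sensitivity SNPs (381, 861, 5808,
    9041). Builds a synthetic surrogate reference with the assay's primer
    footprints planted at their published coordinates, simulates both PCR
    rounds as a strict 3'-match presence/absence amplification model, renders
    virtual gel lanes, calls per-SNP genotypes from band patterns, infers
    diploid H1/H2/H7/H8/H9 haplotype pairs from unphased genotypes (including
    the documented H1H7/H1H9 ambiguity and its resolution policy), classifies
    warfarin dose groups, and computes cohort genotype/haplotype frequency
    tables with Hardy-Weinberg equilibrium tests. Includes a deterministic
    93-subject fixture cohort and a seeded random-mating cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
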