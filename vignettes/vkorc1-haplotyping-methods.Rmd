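---
title: "Methods: in-silico nested ARMS PCR and VKORC1 haplotype inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico nested ARMS PCR and VKORC1 haplotype inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vkhap)
```

## The assay being modeled

Four *VKORC1* SNPs — 381 C>T, 861 C>A, 5808 T>G and 9041 G>A (plus-strand
alleles; each site also has an alternative published coordinate offset by
−85, e.g. 381 ↔ 296) — jointly delineate the five haplotypes H1, H2, H7,
H8 and H9. H1/H2 carriers need low warfarin doses, H7/H8/H9 carriers higher
ones, so a cheap assay that calls all four SNPs at once is clinically
useful.

The assay is a two-round nested multiplex:

* **PCR1** uses three common primer pairs to cut the gene into fragments of
  1060 bp (covering 381 and 861), 398 bp (covering 5808) and 853 bp
  (covering 9041).
* **PCR2** re-amplifies inside those products with allele-specific (ARMS)
  primers whose 3′-terminal base sits exactly on the SNP. The reaction is
  split into a wild-type tube and a mutant tube; a primer whose 3′ base
  mismatches the template cannot be extended, so band presence in a tube
  reports the presence of that allele. The diagnostic band sizes are
  960 bp (381), 480 bp (861), 280 bp (5808) and 434 bp (9041).

`vkhap` reproduces the *logic* of this assay exactly and none of its
kinetics.

## The amplification model

`simulate_round()` emits an amplicon for every (forward site, reverse site)
pair on a template for which

1. both primers match the template **full-length with zero mismatches**,
2. both 3′-terminal bases pair exactly,
3. the forward primer's 3′ end lies strictly upstream of the reverse
   primer's 3′ end, and
4. the product is at most `max_product_bp` long (default 2000 bp, above the
   largest designed product of 1060 bp; the cap is what keeps the three
   PCR1 pairs from producing multi-kilobase cross-products in the
   multiplex).

This is a deliberately strict binary model. The discrimination mechanism of
an ARMS assay is the single engineered 3′ mismatch; the validated assay
showed clean discrimination (sequencing-concordant calls), so we model
extension as all-or-nothing rather than attempting efficiency curves that
the design gives no data to constrain. `find_binding_sites()` exposes a
`max_internal_mismatches` knob (default 0) for exploring degraded
specificity, but amplification always requires a full match — a site with a
mismatched 3′ base is reported (`three_prime_match = FALSE`) and never
extended. Consequences of the model: no leaky mutant bands, no quantitative
band intensity, no primer-dimer artifacts. The documented ~700 bp
nonspecific band that DMSO addition can introduce in the 381 lane is
available as an opt-in cosmetic flag (`default_protocol(noise_700bp =
TRUE)`); it is recorded next to the real bands and can never collide with a
diagnostic size.

Protocol constants (annealing at 63.5/64.8 °C, 25 cycles, 200× inter-round
dilution, 20 µL volumes, per-target primer concentrations) are carried in
`default_protocol()` and echoed into logs and reports so that a simulated
run documents the wet protocol it mirrors, but they have no effect on
outcomes — in a presence/absence model they cannot.

## The surrogate reference

No public sequence is bundled or downloaded. `build_reference()` builds a
synthetic 9500 bp sequence (the largest printed coordinate is 9456) in
which every primer footprint is planted verbatim at its published 1-based
coordinate — minus-strand primers as the reverse complement of their
printed 5′→3′ sequence — and every SNP position carries its wild-type
allele, the rest being seeded uniform random bases. Everything the
simulation measures (product sizes, band presence, genotype and haplotype
calls) depends only on footprint geometry and SNP alleles, so the filler
sequence is irrelevant to results; the seed (default 0) only has to make
runs reproducible.

Two design choices deserve note:

* The wild-type variant of each allele-specific footprint is what gets
  planted, keeping reference = all-wild-type chromosome;
  `apply_alleles()` then instantiates any chromosome by overwriting the
  four SNP bases (validated against each site's two alleles).
* The filler is redrawn (bounded retries) until every primer's *binding
  core* — its sequence with the allele-specific 3′ base excluded — occurs
  exactly once on either strand of both the all-wild-type and the
  all-mutant chromosome. Uniqueness of the core (rather than the literal
  primer) is the meaningful invariant: the mutant primer differs from its
  wild-type sibling only at the 3′ base, so core uniqueness guarantees
  that neither variant can find a stray site on any chromosome the
  simulator can construct. With 18–25-mers against 9.5 kb of random filler
  a collision is already vanishingly unlikely; the check makes it
  impossible.

`validate_annotations()` re-derives all of this as a report (length vs
footprint, planted slice vs sequence, core uniqueness, 3′-anchor identity
against the designated allele) and is run by the acceptance script before
any measurement.

## Haplotype inference

Per chromosome, the haplotyping decision tree is:
381 C → (5808 T → H1, G → H2); 381 T → (9041 G → H9, A → (861 C → H7,
A → H8)). `classify_chromosome()` implements it literally.

Subjects, however, provide *unphased* genotypes. `infer_pairs()` therefore
enumerates all unordered haplotype pairs of a definition matrix and keeps
those that can produce the genotype site-by-site. The matrix encodes the
tree with wildcards at the branches it never consults: H1/H2 are
unconstrained at 9041 and H9 at 861. This wildcard placement is
reverse-engineered, not taken from any published haplotype structure
table: it is the minimal relaxation under which (a) a 381/9041 double
heterozygote is ambiguous between H1H7 and H1H9 — the assay's documented
blind spot, (b) 9041 hom-mutant and hom-wild-type variants of that genotype
collapse to unique H1H7 and H1H9 calls respectively, and (c) an H8H9 call
is possible at all. Wildcards are instantiated independently per site and
per chromosome — the weakest assumption, since the tree supplies no linkage
constraints beyond its own branches. Users studying a different population
structure can pass their own matrix; every inference entry point takes it
as an argument.

Call states: a single compatible pair is `unique`; several, `ambiguous`;
none, `incompatible` (the genotype cannot be produced by any pair, e.g.
861 A/A with 381 C/C); any no-call site short-circuits to `undetermined`
because the tree needs all four sites — we deliberately do not partially
infer. The `assume_h1h7` policy resolves exactly the `{H1H7, H1H9}` set to
H1H7 (the simplification used where H1H9 is essentially absent from the
population); the default policy reports the ambiguity. Dose classes: both
haplotypes in {H1, H2} → `low`; both in {H7, H8, H9} → `high`; one of
each → `mixed`; anything else (including unresolvable ambiguity across
classes — impossible with the default matrix, where {H1H7, H1H9} is
uniformly mixed) → `undetermined`.

Equivalence of the tree and the enumeration is a tested property, in the
only form in which it holds: wherever the enumeration returns a unique pair
of wildcard-free patterns, some phasing of the genotype classifies to
exactly that pair. The two routes intentionally differ elsewhere — the
matrix constrains sites the tree would skip (H1 requires 861 C, so a
381 C / 861 A chromosome is `incompatible` by enumeration even though the
tree, read naively, would call it H1). The matrix is the diploid semantics;
the tree is its single-chromosome shadow.

## The fixture cohort (FC93) and the 861 inconsistency

`fixture_cohort()` returns a deterministic 93-subject cohort whose
inference output is fixed: 50 H1H1, 1 H1H2, 1 unique H1H7, 31 ambiguous
H1H7-or-H1H9, 1 unique H1H9, 8 H7H7, 1 H8H9. The published description of
this cohort gives only per-SNP genotype marginals and those haplotype-call
counts; the joint genotypes bundled here are *derived* — the unique joint
assignment compatible with the default matrix that reproduces the
haplotype counts and the 381, 5808 and 9041 marginals exactly.

The 861 marginal cannot also be matched: the published row reports two
861 hom-mutant subjects and zero heterozygotes, but under the tree every
861 A allele sits on an H8 chromosome, and the published haplotype column
contains a single H8 (in H8H9, which is 861 A/A only if H9's wildcard is
instantiated to A — as FC93 does). Two hom-mutant subjects would require
two H8H8 or H8H9 calls. FC93 follows the haplotype column (92/0/1) and the
discrepancy is surfaced here and in the fixture file header rather than
silently patched. Relatedly, a published HWE note for 861 quotes
"expected = 0.29" for the CA class; no standard formula reproduces that
number (expected heterozygote *count* under HWE with q = 0.0215 is 3.91,
expected *frequency* 0.042), so the package reports the standard
expectation and does not attempt to reproduce the 0.29.

Each FC93 row records the generating haplotype pair and its wildcard fills,
making the fixture a tested fixed point: inference (under `assume_h1h7`)
followed by regeneration from the resolved pairs reproduces the genotype
multiset exactly.

## Cohort statistics

`genotype_table()` and `haplotype_table()` recompute percentages from
counts (never trusting stored percentages), rounding half-up to 2 decimals
to match the conventional "count (percent)" layout; combined percentages
(e.g. "all remaining haplotypes") are computed from summed counts and
rounded once, not by adding rounded rows. `hwe_test()` computes allele
frequencies by gene counting, expected counts (np², 2npq, nq²), and a 1-df
chi-square without continuity correction — standard practice when no test
is otherwise specified — flagging deviation at a configurable alpha
(default 0.05) and setting `small_counts` when any expected cell is below
5. For exactly that small-count situation (861: expected het 3.91,
expected hom-mut 0.04) an exact test on the heterozygote count is provided
(`method = "exact"`, conditional distribution of heterozygotes given the
allele count; p = sum of probabilities of outcomes no likelier than the
observed). Monomorphic sites return χ² = 0, p = 1 by convention.

## The random-mating generator

`sample_cohort(n, hap_freqs, seed)` draws 2n haplotypes independently with
replacement (random mating, hence HWE at the haplotype level), fills
wildcards — by default with the site's wild-type allele (so H1/H2 carry
9041 G and H9 carries 861 C), a deliberately conservative choice given that
the true alleles at unconsulted branches are unknown; any fill can be
passed explicitly — and pairs consecutive draws. The generating pair of
every subject is retained as an attribute, which is what makes
"generation ⊆ inference" a testable invariant rather than a plausibility
argument. The generator emulates genotype sampling only: no genotyping
error, no missingness, no population structure or linkage beyond the
haplotype definitions themselves, so passing tests say nothing about those
real-data phenomena.

## Problem sizes and determinism

All randomness flows through explicit integer seeds (`build_reference`,
`sample_cohort`), implemented with save/restore of the caller's RNG state.
The test suite exercises: all 81 unphased genotypes end-to-end through the
simulator against a brute-force allele-presence oracle (plus phasing
symmetry spot checks), all pattern pairs × wildcard instantiations through
the generation/inference round trip, and HWE calibration on 100 seeded
cohorts of n = 10,000 (deviation rate compared against a ~3-standard-error
binomial envelope around alpha, the narrowest bound a 400-test sample can
honestly support). These sizes were chosen as the smallest that are
exhaustive where exhaustiveness is possible and statistically conclusive
where it is not.

## Known limitations

* Presence/absence amplification: no band intensities, no
  temperature/concentration sensitivity, no cross-dimer or off-target
  screening (the panel is *validated* against the surrogate, not
  re-screened genome-wide).
* The surrogate reference shares only footprints and SNP alleles with the
  real gene; alignment-based workflows cannot be tested against it.
* The haplotype matrix's wildcards are a modeling choice fitted to the
  observed call structure, not measured linkage; conclusions drawn from
  wildcard instantiations should be treated accordingly.
* Statistical phasing (EM and relatives), imputation from additional
  linked SNPs (e.g. the 6484 variant in complete LD with 9041, the natural
  wet-lab fix for the H1H7/H1H9 ambiguity) and dose-prediction equations
  are out of scope.
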