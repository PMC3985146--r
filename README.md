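# vkhap

Warfarin dose requirement is strongly associated with *VKORC1* haplotypes:
H1 and H2 predict low-dose sensitivity, H7, H8 and H9 a higher dose
requirement. A nested allele-specific multiplex PCR assay can delineate all
five haplotypes from just four SNPs — *VKORC1* 381 (C>T), 861 (C>A),
5808 (T>G) and 9041 (G>A) — using only a conventional thermal cycler: an
outer multiplex (PCR1) shortens the genomic template into three fragments,
and an inner multiplex (PCR2), run as separate wild-type and mutant tubes,
places each SNP at the 3′-terminal base of an allele-specific (ARMS) primer
so that a single 3′ mismatch blocks extension.

`vkhap` is the computational counterpart of such an assay, for
pharmacogenetics groups who want to design, sanity-check or teach it without
touching a wet lab:

* a **synthetic surrogate reference** with all primer footprints planted at
  their published coordinates (`build_reference()`, seeded, deterministic);
* an **in-silico PCR engine** with strict 3′-match extension
  (`find_binding_sites()`, `simulate_round()`, `simulate_assay()`), plus
  text gel rendering (`render_gel()`);
* **genotype calling** from tube band patterns
  (`call_genotype_from_bands()`): WT-tube band only → homozygous wild type,
  both tubes → heterozygous, Mut tube only → homozygous mutant;
* **diploid haplotype inference** from unphased genotypes
  (`infer_pairs()`, `classify_chromosome()`): exhaustive enumeration of
  compatible haplotype pairs under a configurable definition matrix,
  reporting the assay's intrinsic H1H7-vs-H1H9 ambiguity (subjects
  heterozygous at both 381 and 9041) and an opt-in `assume_h1h7`
  resolution policy, with warfarin dose-group classification
  (`dose_class()`);
* **cohort statistics**: genotype/haplotype frequency tables
  (`genotype_table()`, `haplotype_table()`, `table3_report()`) and
  Hardy–Weinberg equilibrium tests (`hwe_test()`, chi-square and exact);
* **synthetic cohorts**: a deterministic 93-subject fixture
  (`fixture_cohort()`) and a seeded random-mating generator
  (`sample_cohort()`);
* TSV/FASTA/VCF interchange and a CLI (`vkhap_cli()`,
  `inst/scripts/vkhap.R`).

## The haplotyping model

Each chromosome is classified by a decision tree over the four SNPs:

```
381 C ─ 5808 T → H1          381 T ─ 9041 G → H9
      └ 5808 G → H2                └ 9041 A ─ 861 C → H7
                                             └ 861 A → H8
```

As a diploid matrix over sites (381, 861, 5808, 9041), with `*` a wildcard
at branches the tree never consults:

| haplotype | 381 | 861 | 5808 | 9041 |
|-----------|-----|-----|------|------|
| H1 | C | C | T | * |
| H2 | C | C | G | * |
| H7 | T | C | T | A |
| H8 | T | A | T | A |
| H9 | T | * | T | G |

A pair (Hi, Hj) is compatible with an unphased genotype iff at every site
the observed allele pair can be split between the two patterns. The wildcard
placement is the minimal relaxation that yields the observed ambiguous
class together with unique H1H7, H1H9 and H8H9 calls; it is user-overridable
(`matrix` argument everywhere).

## Worked example

```r
library(vkhap)

ref <- build_reference(seed = 0)           # 9.5 kb surrogate, footprints planted
wt  <- setNames(vk_snp_sites()$wt_allele, vk_snp_sites()$id)
simulate_assay(list(wt, wt), ref)
#> Assay readout for subject1
#>   PCR1 products: 1060, 853, 398 bp
#>   snp expected_bp wt_tube mut_tube
#>   381         960    TRUE    FALSE
#>   861         480    TRUE    FALSE
#>  5808         280    TRUE    FALSE
#>  9041         434    TRUE    FALSE
```

An all-wild-type subject produces the three outer products (1060, 853,
398 bp) and all four wild-type-tube bands (960, 480, 280, 434 bp), and no
mutant-tube band — the 3′-mismatched mutant primers cannot extend.

```r
infer_pairs(c(`381` = "C/T", `861` = "C/C", `5808` = "T/T", `9041` = "A/G"))
#> Haplotype call: {H1H7, H1H9} [ambiguous]; dose class: mixed
```

A subject heterozygous at both 381 and 9041 cannot be phased by the four
SNPs alone: H1H7 and H1H9 are both compatible (both are mixed-dose pairs).

```r
cat(table3_report(fixture_cohort(), policy = "assume_h1h7"), sep = "\n")
#> Genotype frequency of individual VKORC1 SNPs
#> SNP  Homozygous wild type  Heterozygous  Homozygous mutant
#> 381  51 (54.84)   33 (35.48)  9 (9.68)
#> 861  92 (98.92)   0 (0)       1 (1.08)
#> 5808 92 (98.92)   1 (1.08)    0 (0)
#> 9041 51 (54.84)   33 (35.48)  9 (9.68)
#>
#> Haplotype frequency (policy: assume_h1h7)
#> Haplotype  Number of patients (%)
#> H1H1  50 (53.76)
#> H1H2  1 (1.08)
#> H1H7  32 (34.41)
#> H1H9  1 (1.08)
#> H7H7  8 (8.6)
#> H8H9  1 (1.08)
```

On the bundled 93-subject fixture cohort, 53.76% of subjects are H1H1,
34.41% resolve to H1H7 under the `assume_h1h7` policy (1 unique + 31
ambiguous), 8.6% are H7H7 and the remaining 3.23% split across H1H2, H1H9
and H8H9. `hwe_test(c(91, 0, 2))` flags the 861 genotype distribution as
deviating from Hardy–Weinberg equilibrium (observed hom-mutant frequency
0.0215 with no heterozygotes; expected heterozygote count 3.91) — with a
small-expected-cell warning, so the exact test is the better choice there.

The same pipeline from a shell:

```sh
Rscript inst/scripts/vkhap.R make-cohort --fixture --out cohort.tsv
Rscript inst/scripts/vkhap.R infer --genotypes cohort.tsv --policy assume_h1h7 --out calls.tsv
Rscript inst/scripts/vkhap.R summarize --genotypes cohort.tsv --policy assume_h1h7 --out report.txt
```

## Notes and caveats

* Amplification is modeled as presence/absence: annealing temperatures,
  cycle counts, MgCl₂ and primer concentrations are carried as protocol
  metadata (`default_protocol()`) and echoed in logs but never change
  outcomes. Band intensity, primer dimers and leaky 3′-mismatch extension
  are out of scope.
* The fixture's 861 genotype marginal (92/0/1) intentionally differs from
  one published marginal row (91/0/2): that row is irreconcilable with the
  published haplotype-call counts, which admit at most one 861 hom-mutant
  subject. See the methods vignette.
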