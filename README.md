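# opsinmyopia

Analysis toolkit for the association between X-linked cone opsin
(*OPN1LW*/*OPN1MW*) exon-3 haplotypes and common myopia, written for
vision scientists and statistical geneticists working with opsin
haplotype, ocular biometry, minigene splicing, and paired-eye trial
data.

## What it computes

Myopia is driven by excessive axial elongation of the eye. Exon 3 of
the cone opsin genes carries eight SNPs whose haplotypes modulate
exon-3 skipping during splicing; cones expressing strongly skipping
haplotypes are nearly photopigment-free, and a retinal mosaic mixing
such cones with normal ones is hypothesized to generate spurious
contrast signals that stimulate eye growth. The package implements:

* **Haplotype algebra** — parse/validate 8-nt haplotype strings over
  the canonical panel (rs94930, rs713, rs731614, rs5986963, rs5986964,
  rs149897670, rs145009674, rs155715655), translate the five coding
  SNPs to residues 153/171/174/178/180, and enumerate the 128-minigene
  space in which (rs5986963, rs5986964) takes only its two observed
  joint states (A,T)/(G,G).
* **Biometry** — calculated spherical equivalent refraction,
  SER = −(AL × 2.03 + 0.94 × CC) + 88.58 (AL axial length in mm, CC
  keratometry mean in D), plus re-derivation of the coefficients from
  calibration records by OLS.
* **Splicing assay** — % exon-3 skipped = 100·AUC_A/(AUC_A + AUC_T)
  from primer-extension peak areas, replicate averaging, and per-SNP
  Mann–Whitney tests across the 64 matched minigene pairs with
  Bonferroni correction over 7 comparisons.
* **Cohort association** — the study's inclusion filters (flags first,
  then ≥4-subject haplotype groups), tie-corrected Kruskal–Wallis
  across haplotype groups, the rs145009674 A/G dichotomy
  (exact Mann–Whitney for the 12-carrier group), and the skewed
  (≥67%/≤33% L cones) versus balanced cone-ratio comparison.
* **Split-halves ranking** — the resampling risk-ranking: halve the
  cohort (stratified within haplotype), rank haplotypes by mean SER in
  each half (rank 1 = most myopic), average over 2 × 1000
  half-rankings; plus the rank–mean Pearson correlation, per-subject
  variance explained, and the scrambled-label null.
* **Population genetics** — X-linked Hardy–Weinberg carrier
  probabilities (q, 2q(1−q), q²) and attribution of myopia to a risk
  allele via carriers × penetrance / prevalence.
* **Lens trial** — paired-eye crossover analysis: µm/day growth-rate
  slopes per eye, arm summaries, and a paired test on
  experimental-minus-control differences pooled over the 13 + 7
  subject-periods.
* **Synthetic data** — seeded generators for cohorts, assay tables and
  trial trajectories calibrated to the study conditions, so the whole
  pipeline runs and is testable without the undeposited raw data. A
  bundled fixture carries the published 11-haplotype summary table.

## Worked example

```r
library(opsinmyopia)

co <- generate_cohort(seed = 42)          # 413 subjects, 11 haplotypes
head(summarize_groups(co), 3)
#>   haplotype amino  n median_ser mean_ser
#> 1  AACGGTGG MVVVA 12      -4.24    -3.74
#> 2  AACGGTAT MVVIS 23      -2.92    -2.55
#> 3  AACGGCAT MVAIS 30      -2.09    -2.04

allele_dichotomy(co, "rs145009674", "G")
#> Mann-Whitney U (normal approximation), with_G vs without_G at rs145009674
#>   n:       with_G=12  without_G=401
#>   medians: with_G=-4.24  without_G=-1.524
#>   means:   with_G=-3.74  without_G=-1.615
#>   effect (mean difference): 2.125 D
#>   statistic = 1154, p = 0.002129

rk <- split_halves_rank(co, n_iterations = 1000, seed = 42)
rank_mean_correlation(summarize_groups(co), rk)
#> Pearson correlation, haplotype mean SER vs final rank
#>   r = 0.9675, r^2 = 0.9360, p = 1.128e-06 (n = 11)

x_linked_carrier_probs(0.021)
#> X-linked carrier probabilities at allele frequency q = 0.021
#>   male hemizygous carrier: 2.1%
#>   female, one copy:        4.1%
#>   female, two copies:      0.044%

compare_arms(generate_trial(seed = 42))
#> Paired-eye lens trial, per-eye axial growth rates (um/day)
#>   experimental -0.130 +/- 0.267 (mean +/- SE, n = 20 eyes)
#>   control      1.064 +/- 0.220 (mean +/- SE, n = 20 eyes)
#>   experimental - control: -1.195 um/day over 20 pairs, paired t p = 0.003182
```

Reading the output: the synthetic cohort reproduces the study
structure — the 12 MVVVA (rs145009674-G) carriers are about 2 D more
myopic than the rest; the split-halves final ranks track the haplotype
mean SERs; and in the simulated trial the contrast-reducing lens arm
grows an order of magnitude slower than control eyes, with the paired
test on 20 subject-period differences clearly significant. Exact
numbers vary with the seed.

## Package layout

* `R/` — haplotype model, biometry, splice assay, cohort association,
  split-halves ranking, popgen, lens trial, synthetic generators, IO.
* `inst/extdata/` — SNP panel definition and the published
  11-haplotype summary fixture (TSV).
* `vignettes/opsin-haplotypes-and-myopia.Rmd` — the methods vignette:
  models, assumptions, parameter choices, numerical conventions,
  limitations.
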