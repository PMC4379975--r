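# imssr — detection and analysis of imperfect microsatellites

`imssr` is an R package for genome-wide analysis of *imperfect
microsatellites*: simple sequence repeats (SSRs, tandem repeats of
1–6 bp motifs) whose tracts carry positions deviating from the
phase-expected motif base. Motif heterogeneity is a key determinant of
how repeats mutate and persist in genomes, and the package implements
the full analysis chain used in genome-wide surveys of repeat
imperfection — for sequence analysts and molecular-evolution researchers
who want those methods as tested, reusable functions.

## What it does

* **Detection** (`detect_microsatellites`): seed-and-extend search for
  perfect and imperfect SSRs of motif lengths 1–6 under a fixed-penalty
  scoring model — a tract of length *L* with *m* motif mismatches scores
  *S = L − p·m* and is reported when *S* ≥ *S*<sub>min</sub> (defaults
  *S*<sub>min</sub> = 15, *p* = 5; never more than 3 consecutive
  mismatches; tracts begin and end on matching positions; motifs
  primitive; `N` breaks tracts). Under the defaults every reported locus
  below 20 bp is perfect, two mismatches require ≥ 25 bp and three
  require ≥ 30 bp.
* **Mismatch statistics** (`summarize_genome`, `mismatch_rate`,
  `obs_exp_partition`, `abundance_matrix`): per-genome summaries; the
  per-site mismatch rate *r* = Σm / ΣL over imperfect loci; the
  partition of loci by observed vs expected (*e* = *L·r*) mismatches;
  genome × (length, mismatch) frequency matrices.
* **Multivariate tests** (`permanova`, `pairwise_posthoc`, `pcoa`,
  `cap_correlation`): distance-based pseudo-F with unrestricted label
  permutation (exhaustive and exact when feasible), a posteriori
  pairwise *t* = √F comparisons, principal coordinates, and canonical
  analysis of principal coordinates between two distance matrices.
* **SNP overlay** (`map_snps_to_loci`, `classify_m0_m1`,
  `build_contingency`, `yates_chi2`): classify SNPs inside tracts as
  **M1** (all alleles represented among the bases realized at the SNP's
  motif phase) or **M0** (a foreign base), and test association with
  mismatch burden by Yates' continuity-corrected chi-square.
* **Panel utilities** (`find_polymorphic_loci`, `regress_mismatch_on_m1`,
  `generations_to_years`): polymorphic repeat loci across inbred lines,
  OLS of mismatch burden on accumulated M1 mutations (effect reported as
  percent of the mean burden), and floor(g · 36 / 365.25) allele-age
  conversion from generations to years.
* **Synthetic data** (`generate_genome`, `generate_snps`,
  `generate_panel`, `simulate_m1_regression`): seeded genomes with
  planted tracts and exact ground truth (rejection-sampled background,
  sharp tract boundaries), planted M0/M1 SNPs, inbred-line panels and
  regression simulations — everything downstream is testable without
  downloads.

## Worked example

```r
library(imssr)

# a 21 bp AT repeat with one internal mismatch, flanked by other sequence
seqs <- c(chr1 = "TTGATCATATATATATCTATATATATAGCTTAG")
loci <- detect_microsatellites(seqs)
loci
#>   chrom start end motif std_motif motif_len length n_mismatches
#> 1  chr1     6  27    AT        AT         2     21            1
#>   mismatch_positions score is_perfect
#> 1                 10    16      FALSE
```

The tract spans 0-based positions 6–27 (1-based 7–27 on disk), is 21 bp
long, carries one mismatch at within-tract offset 10, and scores
21 − 5·1 = 16 ≥ 15, so it is reported. A 19 bp tract with one mismatch
would score 14 and be invisible — under these search conditions every
reported locus shorter than 20 bp is perfect.

```r
# PERMANOVA in its univariate-Euclidean limit
D <- euclidean_distance(matrix(c(0, 1, 4, 5), ncol = 1))
permanova(D, factor(c("a", "a", "b", "b")), n_perm = 999)
#> PERMANOVA (exhaustive, 6 permutations)
#>  factor df SS pseudo_F   p_value
#>  factor  1 16       32 0.3333333
#> Residual df 2, SS_within 1, SS_total 17
```

The pseudo-F equals the classical one-way ANOVA F (32), and with only 6
distinct label arrangements the permutation p-value is enumerated
exactly: 2 of 6 arrangements reach the observed F, so p = 1/3.

## Layout

```
R/                      implementation
tests/testthat/         unit, property and end-to-end acceptance tests
scripts/acceptance.R    recomputes the analytic bounds (JSON output)
vignettes/              methods vignette (models, choices, limitations)
inst/scripts/           thin command-line wrapper for detection
```
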