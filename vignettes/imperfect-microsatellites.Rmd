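---
title: "Detecting and analysing imperfect microsatellites with imssr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing imperfect microsatellites with imssr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imssr)
```

## The problem

Microsatellites (simple sequence repeats, SSRs) are tandem repeats of
1--6 bp motifs found throughout eukaryotic genomes. A substantial
fraction of them are *imperfect*: individual positions inside the tract
deviate from the base implied by the motif and its phase. Motif
heterogeneity interacts with the mutational dynamics of repeats --
imperfect loci slip less, and the pattern of point mutations inside a
tract determines whether heterogeneity builds up or is erased -- so
genome-wide surveys of mismatch burden, and the relationship between
tract length, mismatch count and genomic abundance, are informative about
how repeats are maintained. `imssr` implements the full analysis chain:
detection of imperfect SSRs under a fixed-penalty scoring model,
mismatch-abundance statistics, permutation-based multivariate tests,
classification of SNPs inside repeats into allele-match types (M0/M1),
inbred-panel utilities, and a synthetic-genome generator with planted
ground truth that makes every step testable without external downloads.

## The detection model

A candidate tract of length $L$ bp carrying $m$ motif mismatches scores

$$S(L, m) = L - p \cdot m,$$

and is reported when $S \ge S_{\min}$. The defaults $S_{\min} = 15$,
$p = 5$ are the conventional search conditions for this analysis
(alternates $S_{\min}=15, p=3$ and $S_{\min}=10, p=5$ are supported via
`detection_params()`). Never more than three consecutive mismatch
positions are allowed, tracts must begin and end on a matching position,
motifs must be primitive (not a power of a shorter motif), and `N`
terminates any tract. Three consequences of the scoring rule are worth
keeping in mind, and are asserted by the test suite: a reported locus
with one mismatch is at least 20 bp long (so every reported locus under
20 bp is perfect), two mismatches require 25 bp, and three require
30 bp.

Detection is seed-and-extend. A *seed* is a maximal perfect tandem run
of a primitive motif with at least `seed_min_copies` (3) full copies and
at least `seed_min_len` (8) bp -- or any perfect run already reaching
`min_score` bp, so that perfect loci of every motif size at the score
threshold are always seeded. Seeds are extended outwards
position-by-position against the phase-expected base, absorbing
mismatches while the consecutive-mismatch cap permits, and the extended
window is trimmed so both ends match and the score is maximal (ties go
to the longer tract). Overlapping candidates are resolved greedily:
higher score first, then smaller motif length, then leftmost start.
Reverse-strand repeats are their own forward-strand repeats; motif
classes are grouped via the canonical motif (`standardize_motif()`, the
lexicographic minimum over rotations and reverse-complement rotations).
Mismatches are substitutions only -- an insertion or deletion breaks
phase and splits a tract, which is the natural semantics for a fixed
per-mismatch penalty with no gap model.

A known limitation of any seeded search: a tract whose *every* perfect
stretch is shorter than the seed requirement is invisible, even if its
score clears the threshold. At the default parameters this requires
mismatches recurring at least every dozen positions for large motifs --
layouts that essentially never arise from point mutations of a
once-perfect repeat, which is the mutational origin the synthetic
generator emulates (and the test suite verifies equivalence against
brute-force enumeration on exactly that tract family, 500 sequences per
run).

Coordinates are 0-based half-open in memory and 1-based inclusive on
disk (`write_loci_tsv()`/`read_loci_tsv()` round-trip exactly). IUPAC
ambiguity codes other than `N` are rejected at input because mismatch
semantics are defined only over unambiguous bases.

```{r detect-demo}
seqs <- c(chr1 = "TTGATCATATATATATCTATATATATAGCTTAG")
detect_microsatellites(seqs)
```

## Mismatch statistics

`summarize_genome()` reports imperfect-locus counts and their share of
all loci and of the genome, with per-chromosome and per-motif-length
breakdowns that always sum to the totals. The genome-wide per-site
mismatch rate is

$$r = \frac{\sum_i m_i}{\sum_i L_i}$$

over imperfect loci (an `scope = "all"` variant divides by all tract
lengths for sensitivity analysis). Each imperfect locus is then compared
with its expected mismatch count $e = L \cdot r$ and partitioned into
*higher than expected* ($m > e$), *lower* ($m < e$) or *equal*
($m = e$). Exact ties are reported separately rather than silently
folded into "lower", so `n_higher + n_lower + n_equal` always equals the
imperfect-locus count -- the identity that published per-species tables
obey. `insect_ssr_counts()` bundles the published 20-species counts; the
Spearman correlation between the higher and lower columns recomputed
from those printed values with mid-ranks is 0.917 (the original report
gives 0.938 with df = 19 for n = 20 species; the difference is flagged,
not resolved -- our tests assert the value recomputable from the printed
columns).

`abundance_matrix()` builds the genome-by-(length, mismatch) frequency
tables that feed the multivariate tests. Length levels are matched
*exactly* (the analysis targets the discrete lengths 20--24 bp and 35,
40, ..., 85 bp rather than bins; a `bin_width` option admits a window
for sensitivity checks), and mismatch levels are either exact counts
(1, 2, 4, 6) or classes such as `list(lt3 = 0:2, ge3 = 3:99)` with a
30 bp length control.

## Multivariate tests

`permanova()` computes distance-based pseudo-F statistics from the
Gower-centred matrix of $-D^2/2$, for one factor or for the main effects
of two crossed factors (no interaction, matching the two-factor
length/mismatch analysis). Significance comes from unrestricted
permutation of object labels; when the number of distinct label
arrangements does not exceed `n_perm` the distribution is enumerated
exhaustively and the p-value is exact, otherwise `n_perm` random
permutations are drawn and $p = (1 + b)/(1 + B)$, which cannot be 0 and
counts the observed statistic among the permutations. On univariate data
with Euclidean distances the one-factor pseudo-F reproduces the
classical one-way ANOVA F to $10^{-10}$; the test suite also
cross-checks against `vegan::adonis2`. `pairwise_posthoc()` reports the
a posteriori $t = \sqrt{F}$ for every level pair on the corresponding
sub-matrix.

`cap_correlation()` implements the canonical analysis of principal
coordinates: both distance matrices are ordinated by `pcoa()` (eigen
decomposition of the Gower-centred matrix; negative eigenvalues are
reported but excluded from coordinates; axes below $10^{-10}$ dropped),
a number of leading axes is retained, and canonical correlation analysis
links the two score sets. The first squared canonical correlation
$\delta_1^2$ is tested by permuting the object order of the second score
set. The retained-axis rule -- smallest number of axes explaining at
least 90% of positive-eigenvalue variation, capped at $n - 2$ -- is our
choice (the source analysis does not state one); the cap exists because
with $n$ axes on $n$ objects the canonical correlation is trivially
perfect.

```{r permanova-demo}
x <- c(0, 1, 4, 5)
D <- euclidean_distance(matrix(x, ncol = 1))
permanova(D, factor(c("a", "a", "b", "b")), n_perm = 999)
```

## SNPs inside repeats: M0 and M1

A SNP inside a tract is classified against the bases *realized at its
motif phase*: the phase-expected consensus base plus the assembly base
at every mismatch offset of the locus sharing that phase. If every SNP
allele (REF and all ALTs) is represented in that variant set the locus
is type **M1** -- the polymorphism toggles between bases already present
in the motif variants; otherwise it is **M0** -- the SNP introduces a
base foreign to the repeat. The per-phase definition matters: a
phase-blind set would mis-classify SNPs at positions whose phase never
carries the mismatch base. For a perfect locus the variant set is the
consensus alone, so any biallelic SNP is M0. When several SNPs hit one
locus, each classification counts once (SNP-level counting; a
`locus_level` option collapses to the majority verdict with ties to M0
-- the source analysis does not state its convention, so both are
available and the default is declared).

`build_contingency()` cross-tabulates M0/M1 against mismatch burden
(< 3 vs >= 3 mismatches, restricted to loci >= 30 bp so that length is
controlled), and `yates_chi2()` applies the continuity-corrected
chi-square

$$\chi^2 = \frac{N\,(\max(0, |ad - bc| - N/2))^2}{(a+b)(c+d)(a+c)(b+d)}.$$

## Panel utilities

`find_polymorphic_loci()` detects tracts on a reference interval and
reads the same interval from each line of a substitution-only inbred
panel (equal-length sequences aligned by construction; indel handling in
real panels is out of scope because the analyses here concern
substitutions). A locus is polymorphic when at least two distinct tract
sequences segregate. `regress_mismatch_on_m1()` fits OLS of mismatch
burden on accumulated M1-type mutations and reports the effect as a
percentage of the mean response, $100\,|\hat\beta|/\bar{y}$ -- the
declared operationalization of "one M1 mutation changes mismatch burden
by X%" (the original regression's response scale is unstated, so
parameter-recovery tests target this definition only).
`generations_to_years()` converts generation counts with
$\lfloor g \cdot d / 365.25 \rfloor$ and $d = 36$ days, the truncating
convention that reproduces both printed endpoints (1,380 generations
$\to$ 136 yr; 1,530 $\to$ 150 yr).

## The synthetic-data generator

`generate_genome()` plants repeat tracts of known motif, length and
mismatch layout in random background (uniform base composition by
default; tracts separated by >= 50 bp). Three design rules make ground
truth exact rather than probabilistic:

* **Mismatch layouts are point-mutation-like.** Sampled offsets keep far
  enough from tract ends that no end-trim improves the score
  ($o_j \ge p\,j - 1$ from both ends), never exceed the
  consecutive-mismatch cap, and leave at least one perfect stretch long
  enough to seed the search. Real imperfect repeats arise by point
  mutation of once-perfect tracts, so retaining a perfect core is the
  realistic regime -- and it guarantees the detector recovers planted
  tracts exactly.
* **Boundaries are sharp.** The two background bases flanking each tract
  are forced to disagree with the phase-expected continuation.
* **Background is rejection-sampled.** The assembled genome is screened
  with the detector; if anything unplanted is detected, or a detectable
  planted tract is not recovered exactly, the background is redrawn.
  False-positive tests on synthetic genomes are therefore exact.

Every generator is a pure function of its spec and seed.
`generate_snps()` plants M1 SNPs (alleles drawn from the variant set at
a mismatch offset) with probability `q` and M0 SNPs otherwise;
`generate_panel()` derives inbred lines with seeded substitutions at
separate in-tract/out-of-tract rates (defaults 0.005/0.001 per site per
line, i.e. segregating variation enriched inside repeats);
`simulate_m1_regression()` plants a known percent-effect (default 56%,
intercept 4, Gaussian noise sd 0.5, M1 counts Binomial(2, 0.25)).

What passing tests on these data do **not** show: behaviour on real
assemblies with indel-rich repeats, assembly gaps beyond simple `N`
runs, compound/interleaved SSRs, or GC-biased backgrounds (an AT-bias
option exists but no test depends on it).

## Numerical and scale choices

* Permutation counts: published-style analyses use 9,999 permutations;
  the test suite uses 19--199 where only correctness of the machinery is
  at stake, and exhaustive enumeration wherever the arrangement count
  permits -- exact p-values do not depend on permutation counts.
* Test problem sizes: oracle equivalence runs 500 sequences of <= 200 bp
  against full enumeration; planted-recovery runs 100 genomes of 10 kb;
  the M0/M1 calibration genome carries 420 tracts (56 kb) so that 2,000
  unique-position SNPs are placeable at every planted M1 fraction.
  These sizes exercise every code path while keeping the default test
  run quick.
* Ties: overlap resolution breaks ties by smaller motif length, then
  leftmost start, then longer tract; trim ties prefer the longer tract;
  observed-equals-expected loci get their own partition bucket;
  locus-level M0/M1 ties collapse to M0. All are deterministic.
* Degenerate inputs error loudly: no imperfect loci (mismatch rate),
  zero-variance vectors (correlation), single-level factors (PERMANOVA),
  zero margins (chi-square), constant predictors (regression).
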