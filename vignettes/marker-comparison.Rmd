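---
title: "Comparing microsatellite and Pool-Seq views of genetic diversity: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing microsatellite and Pool-Seq views of genetic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Population and conservation genetics has long relied on small panels of
microsatellite (SSR) markers to estimate genetic diversity within and
differentiation among populations, implicitly assuming those estimates
track genome-wide patterns. Pooled whole-genome re-sequencing
(Pool-Seq) gives the genome-wide answer directly — per-site allele read
counts for each population pool — at the price of losing individual
genotypes. `poolDiv` implements both estimator families, the statistical
battery needed to compare them on the same populations, and a SNP
down-sampling procedure that answers the planning question "how many
random SNPs are enough?". A synthetic-data generator with recorded
ground truth makes the entire chain testable end to end without any
external data.

# Microsatellite estimators

For each locus and population, with `n` typed diploids and allele
frequencies `p_i` (complete-case within locus: an individual missing at
a locus is dropped at that locus only, the common behaviour of the
classical SSR tools; the data this emulates had only ~0.3% missing
genotypes so the policy is essentially inconsequential):

* expected heterozygosity `SSR-He = 2n/(2n-1) * (1 - sum p_i^2)` (Nei's
  1978 small-sample correction, the standard at n = 20;
  `heBiasCorrection = "raw"` gives the uncorrected gene diversity);
* allelic richness `Ar` = mean observed allele count over loci. No
  rarefaction by default — appropriate when every population is typed
  for the same number of individuals; a hypergeometric rarefaction
  variant (`rarefy = TRUE`) standardises to the smallest sample for
  unequal designs;
* inbreeding: `G_IS = 1 - Ho/Hs`, `Ho` and the unbiased gene diversity
  `Hs` averaged over loci. Significance of heterozygote deficiency by
  permutation: alleles are re-paired at random among individuals within
  the population, which preserves allele frequencies (hence `Hs`)
  exactly and destroys genotypic association. 999 permutations by
  default; p-values use the `(1+b)/(1+m)` estimator so they are never
  zero.
* null alleles: EM maximum likelihood under the classical model
  (visible alleles plus one non-amplifying null, Hardy–Weinberg
  proportions; apparent homozygotes mix true homozygotes and
  null carriers, blanks are null homozygotes). Initialisation r = 0.05
  and observed frequencies; convergence on the log-likelihood
  (tolerance 1e-8) rather than on parameters, because the likelihood is
  the quantity EM monotonically improves. The test suite checks the EM
  against a profile-likelihood grid search with independently optimised
  allele frequencies.
* differentiation: Weir & Cockerham (1984) variance components per
  locus and allele, combined as the ratio of sums over alleles and loci
  (the combination Weir & Cockerham recommend; which combination the
  classical software used is not always documented, so this choice is
  stated rather than assumed). Negative estimates are reported as
  computed — truncation at zero is presentation, not estimation, and
  would bias the marker-type comparisons.

# Pool-Seq estimators

All coverage figures count nucleotide reads only (`A+T+C+G`); `N` and
deletion columns of the sync format are parsed and preserved but never
enter any computation. Coordinates are 1-based inclusive end to end.

## SNP calling

A site is kept iff every pool's coverage lies in `[20, 400]`, the
second-largest allele's summed count across pools is at least 4
(a joint minor-allele frequency floor of 4/360 ≈ 0.011 for nine pools
of 40), and no third allele reaches that count. Genuinely multi-allelic
sites are dropped entirely rather than reduced to their top two
alleles; sub-threshold stray bases (sequencing error) are tolerated.
Per-population frequencies of the globally defined minor allele are
computed from the retained major+minor counts. `SNP-He` is the mean of
`2p(1-p)` over retained SNPs, assuming Hardy–Weinberg equilibrium
within pools.

## Detection-weighted Watterson's theta

A pool does not observe "segregating sites"; it observes sites whose
minor allele drew at least `b` reads. Under the neutral frequency
spectrum (count class `i` of `n-1` has weight `1/i`) with binomial read
sampling, the expected number of detected segregating sites per site
and unit theta is

    D(n, C, b) = sum_{i=1}^{n-1} (1/i) P(b <= X <= C-b),  X ~ Bin(C, i/n)

so `theta_hat = S / sum(D(n, C_site, b))` over a gene's valid exonic
positions corrects simultaneously for pool size and for
coverage-dependent detection; as coverage grows with `b = 1` the weight
recovers the classical harmonic denominator. The correctness reference
is not a third-party tool but an independent Monte-Carlo oracle in the
test suite (simulate the count spectrum, push it through read sampling,
compare detected density to `D` within 1%).

Gene inclusion follows a covered-positions rule: a gene enters the
genome-wide (unweighted) mean when at least 50% of its exonic positions
have valid coverage in **all** populations. A fraction-of-SNPs reading
of gene inclusion would be circular — SNP status depends on the same
thresholds — so positions are the basis here; the fraction and counts
are reported per gene so users can filter differently.

## Pooled Tajima's D

The pairwise-diversity side is computed per site from alleles passing
the minor-count floor, corrected for read sampling (`C/(C-1)`) and pool
size (`n/(n-1)`), and then normalized by a companion detection weight
(the expected per-site pi per unit theta within the same detection
window). Without that normalization the count floor truncates pi's
expectation by about 4% at 60x, which alone would push neutral mean D
to about −0.16; with both sides normalized, neutral simulations centre
at 0.00 (2000 genes, |mean D| < 0.02). The variance uses the classical
Tajima approximation evaluated at an effective sample size
`min(poolSize, mean valid coverage)` (coverage floor `poolSize/3`,
i.e. 13x for pools of 40); no exact pooled variance exists, so D values
are labelled approximate in all output.

## Pooled pairwise FST

Two per-SNP statistics are available.

The plain heterozygosity partition `(H_T - mean(H_S))/H_T` computed
from read frequencies (`estimator = "nei"`) is what window-averaging
Pool-Seq pipelines report. It is, however, structurally unable to
estimate the drift parameter: for two demes its parametric value is
`F/(2-F)` (about half of F), and read/pool sampling noise adds a floor
of roughly `p(1-p)(1/n + 1/C)` to the numerator — about +0.02 at 40
genomes and 60x. The two distortions partially cancel near F = 0.05,
which makes the estimator look unbiased exactly where this study
design sits, and badly biased elsewhere (at F → 0 it reports ~0.02).

The default (`estimator = "hudson"`) is therefore the Hudson/Bhatia
form `1 - Hw/Hb`: within-pair heterozygosity
`Hw = mean_j 2 q_j (1-q_j) * C_j/(C_j-1) * n/(n-1)` (the two factors
make it unbiased for the population heterozygosity under binomial read
and pool sampling) against between-pair heterozygosity
`Hb = q1(1-q2) + q2(1-q1)` (already unbiased). Its expectation equals
the Balding–Nichols F across the whole range (Monte-Carlo bias ≤ 0.003
for F in [0, 0.09]), with no noise floor at F = 0. SNPs combine by
ratio of sums (the combination recommended for Hudson-style
estimators); the mean of per-SNP ratios is offered too, and is visibly
depressed by low-frequency SNPs — the reason high-coverage Pool-Seq
FST sits below microsatellite FST, and a property the test suite
asserts.

# The comparison battery

Pearson/Spearman correlations (two-sided, t-approximation on n−2 df),
paired t-tests on per-population or per-pair values, pairwise Wilcoxon
signed-rank tests across populations on per-locus heterozygosities
(zero differences dropped, exact p up to 25 informative pairs without
ties, normal approximation with continuity correction otherwise,
Bonferroni over all population pairs), Mantel tests between FST
matrices (lower-triangle Pearson correlation, joint row/column label
permutation of the second matrix, 1001 permutations, one-sided for
positive association — the direction every marker-comparison use of the
test takes; a two-sided flag exists), and a Tajima's-D-versus-zero test
implemented as a Welch two-sample t-test against a same-size
`Normal(0, sd(observed))` pseudo-sample whose seed is recorded in the
result. The two-sample form is deliberately non-standard but kept as
the primary variant for fidelity to the classical workflow this package
re-implements; `oneSample = TRUE` gives the conventional test. The
pseudo-sample size is set equal to the observed sample size and
recorded in output metadata. One tie-handling subtlety: when all
informative differences share a sign, the signed-rank statistic is at
its extreme and the exact two-sided p is `2/2^n` whether or not the
absolute differences are tied, so that case is computed directly
(`stats::wilcox.test` would decline the exact path).

# SNP down-sampling

For each subsample size `k` on the grid (100..10,000 by 100, then to
400,000 by 1,000, truncated to the panel), 1000 replicates draw `k`
SNPs uniformly without replacement — the same indices for every
population within a replicate, so curves are comparable across
populations — and record per-population mean `2p(1-p)`. The 95%
interval is the 2.5–97.5 percentile band of replicate means: the
distribution-free choice, matching the visual confidence bands such
curves are drawn with (a normal approximation would be the only other
defensible reading). Implementation note: each replicate draws one
permutation and reads every grid value off prefix cumulative means;
marginally each `k` still gets an exact uniform `k`-subset, at one pass
per replicate.

Threshold reporting follows two criteria: the smallest `k` at which the
CI half-width is at or below ±0.01 / ±0.005 / ±0.001 simultaneously for
all populations (per-population values are also emitted, since the
simultaneous reading is the stricter of the two defensible ones), and
the smallest `k` at which all population pairs have non-overlapping
CIs, with pairs whose full-data He differ by at most 0.0005 declared
indistinguishable and exempted (0.0005 = equality at the third printed
decimal, the resolution at which such ties are reported; exposed as
`tieTolerance`).

# The synthetic-data generator

`simConfig()` defaults encode the emulated study structure: nine pools
of 20 diploids (n = 40), ~60x Poisson coverage per pool (the study
range is 53–69x), theta = 0.009 over 2000 single-exon genes of 500 bp
(≈5×10^4 emitted SNPs — the full study's 2×10^6 scaled to desk size),
per-population drift F from 0.02 to 0.09 (pairwise FST ≈ (F_i+F_j)/2
spans the study's 0.02–0.09), sequencing error 0.001 with errors
assigned to a uniformly chosen different base (so tri-allelic artifacts
exist for the filter to reject), and 12 cross-species + 7
species-specific SSR loci with ancestral allele counts 2–5 vs 5–10
(the ascertainment contrast) for 20 diploids per population.

Three calibration choices deserve explanation:

* **SFS law.** The ancestral minor-allele law is the folded neutral
  spectrum, density ∝ 1/p on `(pMin, 1-pMin)` with
  `pMin = 1/(nPopulations*poolSize)` (one copy in the total sample).
  Folding matters: a law truncated at 0.5 would lack the high-count
  classes that the detection weight normalizes against, biasing
  theta-hat by −19%; with the folded law the residual truncation bias
  is −1.4%. Because the floor couples to the population count, runs
  that reduce the number of pools for cost should pin `pMin` at the
  study value (1/360).
* **SSR drift spread.** `ssrFst` defaults to 0.12–0.22 across
  populations. This reproduces three study-level facts at once: mean
  pairwise Weir–Cockerham SSR FST ≈ 0.17; an **observed** per-population
  SSR-He spread of roughly 0.32–0.47 for a 19-locus panel; and the
  variance-bias behaviour — after Bonferroni, pairwise Wilcoxon tests
  find no significant population differences in ≥80% of runs, because
  at 19 loci the observed spread is mostly marker sampling noise. A
  naive calibration that treats the observed spread as true spread
  (F ≈ 0.10–0.35) overshoots: consistent per-pair differences then make
  most runs significant.
* **Population diversity differences on the SNP side** come from the
  per-population drift vector (expected SNP-He scales with `1-F_j`), so
  ranking questions are well-posed under the defaults.

What the generator deliberately does **not** emulate: linkage and
recombination (sites are independent — adequate for genome-wide panels
where linked-site effects average out, and consistent with treating
every 50th-SNP subsets as interchangeable with full panels);
demographic trajectories (spectrum skew is produced directly via a
Beta ancestral law — when exercising Tajima's D sign behaviour, note
that only skew among *detectable* frequencies matters, e.g.
Beta(0.8, 10); mass below the detection floor never reaches the
statistics); GC/position-dependent error structure; and allele-size
homoplasy or stutter in the SSR chain. Passing recovery tests
therefore demonstrate estimator correctness under the sampling chain,
not robustness to those real-data features.

Determinism: one global seed; each stage derives a child seed from the
seed and the stage name, so identical configurations give byte-identical
outputs and stages can be re-run in isolation.

# Known limitations and problem sizes

* Both detection weights assume the neutral count spectrum. Under
  Balding–Nichols drift the within-population spectrum departs from
  1/i, giving theta-hat an O(F) model bias (about +5% at F = 0.05
  against the realized perfect-detection Watterson expectation). This
  is intrinsic to spectrum-assuming pool corrections, not an
  implementation artifact; the recovery suite therefore measures the
  correction at negligible differentiation (F = 0.005) and treats the
  drift sensitivity as a documented limitation.
* With the spectrum truncated at `pMin = 1/360`, the singleton class is
  depleted and theta acquires a mild intrinsic coverage dependence
  (−1.4% when doubling 60x to 120x); the coverage-invariance check
  accordingly runs with `pMin = 1e-4`, where the effect vanishes.
  Sequencing-error false positives also scale with coverage at a fixed
  count floor.
* Pooled Tajima's D uses the classical variance at an effective sample
  size; its absolute scale is approximate and only signs, rankings and
  against-zero tests should be interpreted.
* The recovery and behaviour suites run at fixed problem sizes chosen
  for tight Monte-Carlo error at desk scale: 2000 genes × 500 bp
  (two pools) × 20 seeds for theta; 9 pools × 5×10^4 SNPs × 20 seeds
  for FST; 200 diploids × 20 seeds for the null-allele EM; one
  5×10^4-SNP panel × 1000 replicates with the grid truncated at
  4×10^4 for down-sampling; 100 seeds (19 loci) and 15 seeds (200
  loci) for the variance-bias and rank-recovery behaviour. The
  absolute SNP-count thresholds of the emulated study (k at ±0.01 etc.)
  depend on its unpublished empirical per-SNP He distribution and are
  not reproduction targets, though the scaled panel lands at the same
  order of magnitude.
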