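---
title: "ProteoNet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ProteoNet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ProteoNet implements a signed weighted correlation network analysis of CSF
proteomic abundance profiles, together with the downstream comparisons such
an analysis feeds: module-phenotype testing, differential correlation,
hypergeometric enrichment, cross-network module preservation, and
random-intercept mixed-model screening of longitudinal trajectories. This
vignette records the statistical model behind each stage, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic validation data do and do not establish.

## The data model

The central object is a proteins-by-samples abundance matrix
(`ProteinAbundance`, a thin `SummarizedExperiment`) with a scale flag.
Raw (linear-scale) abundances must be strictly positive; the natural log is
taken before any statistics, because per-sample normalization and Pearson
correlation both behave better on the log scale, where multiplicative
sample effects become additive. Missing values stay missing throughout: no
imputation is performed except inside eigenprotein computation (see below),
and all correlations use pairwise-complete observations.

Sample metadata carry subject, group, visit and months from baseline.
Group labels are arbitrary strings; the reference (control) group is named
in configuration, never hard-coded. Visit 1 is anchored at 0 months and
each subject's visits must advance strictly in time.

## Preprocessing

**Missingness filter.** A protein is removed iff its missing fraction
exceeds 0.5 (strictly) in at least one group. The per-group rule protects
proteins that are absent in one condition but quantified elsewhere from
silently biasing group comparisons.

**Background normalization.** The 90% of proteins with the lowest variance
across samples form a background set. Each sample is centered to the median
of its observed background values and scaled by the median absolute
deviation (MAD) from that median. The MAD is used *without* the 1.4826
Gaussian consistency factor: the intent is a literal median absolute
deviation, not a robust standard-deviation estimate. After normalization
every sample's background median is exactly 0 and its background MAD is
exactly 1; both post-conditions are asserted in the test suite to machine
precision, and the map is idempotent.

Two axes are defensible for the MAD step (per sample over background
proteins, or per protein over samples); per-sample scaling, parallel to the
per-sample centering, is the default, and a per-protein mode is available
via `axis = "protein"`.

A consequence worth knowing: per-sample centering subtracts a different
constant from each sample, which is *not* correlation-neutral. It removes
global sample effects (loading, dilution) that would otherwise inflate all
pairwise correlations, at the price of inducing a small negative coupling
across proteins. The test suite demonstrates both facts rather than
pretending centering is invisible to correlations.

**Outlier samples.** Samples are clustered hierarchically (average linkage)
on missing-aware Euclidean distance, and a sample is excluded when the
robust z-score (median/MAD) of its mean distance to all other samples
exceeds 3.0. Two caveats are deliberate:

* A per-sample z > 3 rule applied to n samples flags *some* sample in
  roughly n x 0.13% of clean datasets even in the Gaussian ideal, more in
  small cohorts where the MAD is noisy. The threshold is a screening
  device, configurable and logged, not a calibrated test.
* The default stage order is filter, then normalize, then outlier-detect.
  Purely affine sample distortions (a global shift or rescaling) are
  removed by the normalization, so they are only detectable if outlier
  screening is run *before* normalization; the pipeline records both
  orderings' reports. Real outliers usually distort more than the first
  two moments, so the default order is kept.

## The signed weighted network

Pairwise Pearson correlations are computed over complete pairs, with the
complete-pair count n_ij recorded per entry. Entries with fewer than
`minPairwiseN` (default 10) complete pairs, or touching a zero-variance
protein, are flagged undefined and enter the adjacency at the neutral
weight r = 0 with a warning.

The signed adjacency is a_ij = ((1 + r_ij)/2)^beta with beta = 7. The map
sends r = -1 to 0, r = 0 to 0.5^7 ~ 0.0078 and r = 1 to 1, preserving
correlation sign while the power suppresses weak edges without a hard
threshold. Clustering dissimilarity is d = 1 - a by default; the
topological overlap alternative
t_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) (u != i, j)
is available because it is the field's common default and coincides with
the adjacency mode on block-diagonal networks.

**Module detection.** Proteins are clustered by average linkage; the tree
is cut adaptively at a fraction (default 0.97) of its maximum merge
height; clusters of at least `minModuleSize = 5` proteins become modules
and everything else is unassigned (label 0). Modules whose eigenproteins
are closer than the merge threshold (1 - r < 0.05) are then merged
iteratively, recomputing eigenproteins after each merge, and final labels
are 1..M by decreasing size. Design notes:

* The adaptive fraction-of-maximum cut is a deliberately simple stand-in
  for the dynamic hybrid tree cut: it keys the cut to each dataset's own
  merge-height scale instead of a fixed absolute height, which is the
  property that matters for the data regimes exercised here. A static
  absolute cut is available (`staticCutHeight`).
* The merge threshold 0.05 is interpreted as an eigenprotein-dissimilarity
  merge height. As a static cut on correlation dissimilarity 0.05 would be
  implausibly aggressive (it would demand within-cluster adjacency above
  0.95); as a merge threshold it is a standard, conservative value. The
  static interpretation remains available through configuration.

**Eigenproteins.** Each member protein is median-imputed (its own median,
missing entries only), standardized to mean 0/variance 1, and the module's
first principal-component score vector, scaled to unit variance, is the
eigenprotein. Its sign is chosen so that correlation with the module's
mean standardized profile is non-negative, making "module up" mean
"members up". Variance explained is the leading eigenvalue fraction.

**Connectivity and hubs.** kIn_i sums a protein's adjacency to the other
members of its module; the top ceiling(10% x size) by kIn are hub
proteins, ties broken by protein identifier for determinism. Unassigned
proteins have kIn 0 and are never hubs.

**Stability.** The network is rebuilt with one uniformly chosen sample
left out; iteration modules are matched to the reference partition by
greedy maximum-Jaccard label matching, and a protein scores a match when
its mapped label equals its reference label (unassigned matching
unassigned; proteins of unmatched iteration modules never match). The
per-protein stability is the matched fraction over iterations. The
reference uses all samples.

## Group comparisons

**Eigenprotein tests.** Each non-reference group is compared with the
reference by a two-sided Mann-Whitney U test per module — never disease
versus disease. The exact null distribution is used when both groups have
at most 12 samples without ties; otherwise the normal approximation with
tie and continuity correction. Raw p-values are reported for this small
test family; completely tied data carry no evidence and return p = 1.

**Differential correlation.** Within-group correlation profiles
(pairwise-complete, per-group counts) are compared by Fisher's r-to-z:
Z = (atanh(r_ref) - atanh(r_dis)) / sqrt(1/(n_ref - 3) + 1/(n_dis - 3)),
two-sided normal p, BH-adjusted over all tested pairs at alpha = 0.1. All
pairs defined in both groups are tested by default (a within-module
restriction is available), each group's n being its own complete-pair
count. Pairs with n <= 3 are skipped and counted. Correlations are clamped
away from +/-1 by 1e-15 so that the transform stays finite on degenerate
noise-free fixtures.

**Enrichment.** Foregrounds (dyscorrelated proteins, rising/falling
proteins, or module memberships) are tested against sets (module
memberships or user GMT sets) by the upper-tail hypergeometric
probability, the background being all proteins (or genes after
abstraction) that entered the network. The odds ratio is the sample odds
ratio of the 2x2 table with Haldane-Anscombe 0.5 correction when any cell
is zero. Proteins are abstracted to genes through a many-to-one map; a
gene whose proteins span modules takes its highest-kIn protein's module.
Cross-network preservation tests every module pair of two assignments on
their identifier intersection, BH-adjusted across the grid.

## Longitudinal screening

Per protein, observations from subjects with at least two visits enter a
random-intercept, fixed-slope model
y_it = b0 + b_i + b1 t_it + e_it, b_i ~ N(0, sigma_b^2), fitted by REML,
with time anchored in months from each subject's first visit. The slope's
denominator df is n_obs - n_subjects - 1: the inner-outer rule assigns a
within-subject covariate's df to the within stratum. The natural log scale
is used (recorded in the output); a protein needs at least 5 subjects with
2+ observed values to be fitted (configurable), and the zero-residual
limit falls back to the equivalent fixed-effects estimator, flagged in the
output. Slope p-values are BH-adjusted across fitted proteins and proteins
are classified increasing/decreasing at adjusted p < 0.1.

## The synthetic study fixture

`defaultStudyFixture()` emulates the structure the analysis assumes, at
the scale of a three-group CSF cohort: 41/20/19 subjects (disease,
control, second disease), 870 proteins of which 756 lie in 10 planted
modules with sizes 183 down to 7 and 114 are noise.

The generative model is a per-module one-factor model: protein i of
module m has x_ij = mu_i + lambda (f_mj + delta_gm) + sigma_u eps_ij with
lambda = sqrt(0.75) (so same-module pairs correlate at ~0.75) and unit
total variance. Three modules carry latent group shifts (module 2 down in
the disease group, modules 4 and 9 up; module 9 also up in the second
disease group); shift magnitudes are 1.0-1.5 latent standard deviations,
chosen once so that planted effects are detectable at these group sizes —
the point of the fixture is to verify recovery of effects the study design
can support, not to probe the detection boundary. Ten protein pairs in two
smaller modules are decorrelated in the disease group by resampling the
first protein's factor path there, which removes the co-correlation while
preserving the marginal variance — deliberately distinct from an abundance
shift. Twenty disease subjects carry 2-5 six-monthly visits (attrition
20/12/10/2), with 15 proteins declining and 10 rising at 0.04 log units
per month. Missingness is MCAR per group (3%/2%/3%) with 18 extra
high-missingness proteins exercising the filter, and three samples receive
a +4 SD global shift as planted outliers.

Two realism choices matter for the longitudinal stage: a subject's module
factor persists across visits (per-visit innovation sd 0.3), and 70% of a
protein's unique variance is subject-level. Both express the same
assumption the random-intercept model makes — protein levels are
subject-stable — and leave the baseline-only (cross-sectional) structure
unchanged.

What the fixture does *not* emulate: batch structure, intensity-dependent
missingness (available as an option but off by default, since the study
design gives no mechanism), peptide-level quantification noise,
heavy-tailed abundance distributions, and correlated module factors.
Passing recovery tests on this fixture therefore demonstrates the
pipeline's correctness under its own assumptions, not robustness to every
failure mode of real LC-MS data.

## Validation scales and expectations

The test suite and the acceptance script use these problem sizes, chosen
to exercise the full pipeline at the study's natural scale while staying
fast: full-fixture runs (~870 x 80 baseline) for module recovery (ARI
against planted truth, median over seeds), 2000-pair null simulations for
differential-correlation calibration, 200 replicates for mixed-model slope
recovery and CI coverage, and 3-5 fixture replicates for the longitudinal
screen's error rates.

Three statistical facts shape what the tests assert:

* Under the complete null, BH makes at least one discovery with
  probability exactly alpha, so an all-null screen is "clean" in ~90% of
  runs at alpha = 0.1 — an expectation, not a bound; tests allow binomial
  slack around it.
* A per-sample robust z > 3 outlier rule has a run-level false-flag
  probability that grows with the number of samples; tests assert the
  achievable rate, and the planted-outlier test asserts detection, not
  exactness.
* A planted decorrelated pair's Z statistic is approximately N(3.3, 1)
  under the fixture's design, against a top-1% threshold near 2.7; the
  planted *set* (its median |Z|) reliably ranks in the top 1%, individual
  pairs only with ~0.7 probability, and the tests assert the former.

## Known limitations

Module detection uses a simplified adaptive cut rather than the full
dynamic hybrid algorithm; extremely nested or chained module structure may
be split differently. The stability resampling leaves out a single sample,
matching small-cohort practice, and is not a general bootstrap. The
enrichment odds ratio convention (sample OR with Haldane correction) is
one of several in circulation; background size is always an explicit
input, as results are sensitive to it. Eigenprotein median imputation is
adequate at the low missingness rates the filter guarantees but would bias
results if the filter were relaxed substantially.
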