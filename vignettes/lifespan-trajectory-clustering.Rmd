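---
title: "Clustering lifespan trajectories of memory-encoding activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering lifespan trajectories of memory-encoding activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the data

Episodic memory is among the most age-sensitive cognitive abilities, and a
recurring debate is whether its decline in older age reflects late-life
specific mechanisms (compensatory over-recruitment, reorganization) or the
tail end of trajectories that start in childhood. One way to address this
with cross-sectional task-fMRI is to fit, for every brain region, the full
lifespan trajectory of encoding-related activity and then group regions by
the *shape* of those trajectories: if the resulting clusters are explained
by developmental and evolutionary gradients rather than by patterns that
emerge only in older age, that argues for lifespan continuity.

`lifetraj` implements that analysis for ROI-tabular data. The inputs are:

* a subject table (`subject_id`, `age` in years, `sex`, optional
  `mean_motion`, a DVARS-like scalar per subject);
* a subjects × ROIs activity matrix, one subsequent-memory contrast value
  per cell (source-vs-item encoding effect, percent signal change);
* per-subject trial tables from the branching source-memory test;
* covariate tables (cognitive scores, grey-matter component loadings) and
  ROI-level brain-organization maps.

Imaging preprocessing, first-level GLMs, and the derivation of grey-matter
components are upstream of the package and out of scope.

## Behavioral scoring

Old-item test trials branch: Q1 "have you seen this item?" (yes/no); after a
Yes, Q2 "do you remember what you were supposed to do with it?" (yes/no);
after a Yes, Q3 forces a choice between the two encoding actions. The
outcome categories are *source* (yes, yes, correct), *incorrect source*
(yes, yes, incorrect), *item* (yes followed by no or by a non-response),
*miss* (no), and *no response*. Because Q3 is a two-alternative choice,
source-correct responses occur at chance 0.5 given yes/yes; the corrected
index `(n_source − n_incorrect_source)/n_old` removes that guessing
component, is a proportion in [−1, 1], and equals 0 in expectation for
chance-level responders. Under the branching design exactly seven response
triples are syntactically valid; the classifier rejects branch-inconsistent
input (e.g. a Q3 response after a No at Q2) instead of guessing.

Two reading choices deserve note. First, "incorrect source memories" is
implemented as (yes, yes, incorrect) — the only reading consistent with the
0.5-chance correction. Second, the exclusion rule ("fewer than 6 trials in a
condition of interest") counts the *conditions* that enter first-level
modelling: source, and item *including* incorrect-source trials.

## Trajectory fitting

Each ROI's activity is fit with a generalized additive model: a penalized
cubic regression spline of age with basis dimension 10 and an additive sex
term, smoothing parameter by REML. Basis dimension 10 ("knots = 10" in the
field's shorthand) caps the estimated degrees of freedom (edf) of the smooth
at 9; REML is preferred over GCV for its resistance to undersmoothing. One
outlier pass removes observations with |residual| > 4 residual SDs and
refits once — a single pass, not iterated, so the rule cannot cascade; with
clean data it is a no-op and the threshold `Inf` returns the original fit
unchanged. The fitted curve is evaluated on 100 equispaced ages spanning the
observed age range (the refit keeps the full-sample grid so curves remain
comparable), and the derivative is taken by central finite differences
(one-sided at the endpoints) — numerical rather than analytic
differentiation keeps the operation basis-agnostic, and central differences
are exact for quadratics at interior grid points.

ROIs without evidence of subsequent-memory activity are set aside before
clustering ("cluster 0"). Evidence is the union of two tests per ROI — a
nonzero model intercept (a mean contrast different from zero at reference
sex) and the approximate F test of the age smooth — each corrected by
Benjamini–Hochberg FDR across the ROI family at α = 0.05. The union is
deliberate: a region can carry a constant memory effect with no age
modulation, or an age-crossing effect with zero mean, and both belong in the
clustering.

## Derivative dissimilarity and k-medoids

The dissimilarity between two retained ROIs is the least-squares sum of
their derivative curves over the 100-point grid. Using derivatives removes
the intercept, so two regions with identical trajectory shapes group
together regardless of whether their memory effects are positive or
negative; adding a constant to an ROI's activity column provably changes
neither the dissimilarity matrix nor the resulting partition.

Partitioning uses PAM k-medoids on the precomputed dissimilarities. Plain
deterministic BUILD+SWAP turns out to terminate in a non-global (though
1-swap-optimal) solution on roughly 8% of small random instances — a
measured property of the algorithm, not an implementation artifact. Since a
clustering result should not depend on initialization luck, `pam_fit()` runs
BUILD+SWAP plus 20 random-restart SWAP descents under a locally fixed (and
afterwards restored) RNG seed and keeps the best objective, with the BUILD
solution winning ties. The procedure is therefore deterministic end to end,
and on instances small enough to enumerate it matches the exhaustive-search
optimum in all 800 checked cases. Cluster labels are canonicalized by
descending cluster size, since the raw numbering of a k-medoids run carries
no information.

The number of clusters is chosen by the average silhouette width
`s(i) = (b(i) − a(i))/max(a(i), b(i))` over k = 2…10 (singleton clusters
score 0); the full silhouette profile is returned so alternative local
optima can be reported alongside the winner.

Two stability harnesses mirror common practice: a half-split replication
(subjects split in halves stratified by age decile × sex — the stratification
is a package choice, seeded — with the full pipeline rerun per half and
agreement scored by the adjusted Rand index over ROIs retained in both), and
a motion sensitivity check that drops the `ceiling(0.10 n)` highest-motion
subjects and compares the rerun against the full solution.

## Cluster scores, associations, enrichment

Per cluster, subjects are scored by the first principal component of the
column-centered cluster submatrix, sign-oriented to correlate positively
with the cluster's mean activity; scores are centered by construction and
invariant to constant shifts of the submatrix. Associations with cognition
and grey-matter loadings use `score ~ s(age) + s(covariate) + sex` with an
extra wiggliness penalty (gamma = 2), reporting the covariate smooth's
approximate F, p and edf. Age is always in the model, so the covariate term
is a partial effect. Exact small-sample behavior of penalized-smooth tests
is approximation-dependent, so the package's guarantees are calibration
guarantees, verified by simulation: under the null the reported p-values are
approximately uniform. FDR families are passed explicitly (the analysis that
motivated the package reports family sizes like 24, 12 and 18 alongside each
test), rather than inferred silently from however many p-values happen to be
in hand.

Map enrichment asks, per cluster and map, whether the cluster's mean map
value differs from the mean over all other retained ROIs. The null permutes
cluster labels over ROIs, preserving cluster sizes; the two-sided p-value is
`(1 + #{|null| ≥ |obs|})/(n_perm + 1)`, which can never undercut
`1/(n_perm + 1)`. The "difference" statistic (cluster mean minus the mean of
the rest) is a package decision — the choice is deliberately the simplest
location contrast, and pairwise cluster-vs-cluster contrasts were left out
to keep the family interpretable. Maps with skewed marginals (evolutionary
expansion is approximately exponential) are mid-rank-transformed first,
which makes the p-values invariant to any strictly monotone re-expression of
the raw map. Subcortical ROIs carry `NA` in surface-only maps and are
dropped per map. Plain label permutation is used, not
spatial-autocorrelation-preserving nulls; with ROI-level (not vertex-level)
data and the cluster-mean statistic this matches the design being emulated,
but it does not protect against smooth spatial confounding.

## The synthetic world

The generator's defaults are a single, fixed stated world, used by the test
suite and the acceptance script:

* cohort of n = 300 (full scale 540 available by argument), ages uniform on
  [6, 82] — the real cohort's age distribution is not public, so uniform is
  a neutral default, configurable but not claimed faithful; sexes balanced
  in expectation; mean motion follows a U-shape in age with a steeper
  childhood limb (coefficients 2.5 vs 0.25 on the squared distance from the
  trough at normalized age 0.35), log-normal noise keeping it positive;
* 120 ROIs in six blocks — 20 null and 40/20/16/14/10 across the five
  canonical shapes, roughly the relative sizes a 416-ROI solution reports
  (74/212/50/47/20/13);
* canonical shapes as fixed closed forms of normalized age a ∈ [0, 1]:
  monotonic `a`, U-shape `(2a−1)²`, inverted-U `1−(2a−1)²` scaled ×0.4
  (weak) or ×1.0 (steep), plateau `min(a/0.3, 1)`, null ≡ 0 — smooth,
  reproducible proxies for the qualitative trajectory classes reported in
  this literature, with a *common* amplitude of 0.5 percent signal change
  (the weak/steep distinction lives in the ×0.4 factor; scaling them
  separately would collapse the two into proportional derivative curves);
  baselines (−0.10, −0.45, 0.05, 0.05, 0) give the U-shape cluster its
  negative memory effects;
* activity noise SD 0.125 = 0.25 × amplitude; behavioral signal an
  inverted-U with a 2% non-response rate; grey-matter components with age
  R² 0.86 (monotone-decreasing mode) and 0.46 (inverted-U mode); maps with
  a 1-SD enrichment of the steep-inverted-U cluster.

What the generator does *not* emulate: spatial correlation between ROIs
(columns are conditionally independent given age), heteroscedasticity across
age, non-uniform age sampling, subject-level confounding between motion and
activity, and item-level difficulty structure in the trials. A green test on
this world therefore establishes correctness of the machinery and
calibration of the tests, not robustness to those real-data features.

## A known, instructive limitation

The effect flag controls FDR at 0.05, so by design a few truly null regions
survive it (about 8% of nulls, given the union of two tests and the BH
threshold inflation caused by the many strong effects). Their derivative
curves are all near zero, hence extremely similar to *each other* — and the
silhouette criterion then happily gives them their own small cluster. On the
reference fixture (seed 1) this yields k = 6: the five planted families
recovered exactly (adjusted Rand index 1.0 against planted labels) plus a
three-ROI cluster of leaked nulls, with silhouette 0.903 vs 0.879 at k = 5.
The same happens in both half-split halves, and at other seeds whenever two
or more nulls leak. The practical reading for real data: a very small,
very tight cluster sitting near zero derivative is a fingerprint of
effect-flag false positives, worth inspecting rather than interpreting as a
biological trajectory family.

## Numerical choices and degenerate inputs

Constant age is rejected as rank-deficient; missing ages or activity are
errors, not silently dropped. Smooth p-values are clamped into (0, 1] (the
flag and FDR stages require strictly positive p). A covariate identical to
age does not crash the association stage — the design is rank-deficient and
the shared signal may split between the two smooths, so only the validity of
the report is guaranteed there, not its attribution. All generators are
deterministic given their seed; `pam_fit`'s internal restarts use a fixed
private seed and restore the caller's RNG state, so no package function
perturbs user-level reproducibility. Silhouette selection breaks exact ties
toward the smaller k. The k = n partition is permitted (objective 0,
silhouettes undefined and reported as `NA`) but excluded from selection.
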