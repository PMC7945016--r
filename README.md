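# lifetraj

Lifespan trajectory clustering of regional memory-encoding activity.

`lifetraj` is an R package for asking how the brain activity that supports
successful episodic memory encoding changes from childhood to old age, and
whether regions can be grouped by the *shape* of that change. It targets the
common study design in lifespan cognitive neuroscience where each subject in
a wide age range (e.g. 6–82 years) performs an encoding task in the scanner,
and each region of interest (ROI) yields one subsequent-memory contrast value
per subject (source-vs-item encoding activity, in percent signal change).
Everything in the package is ROI-tabular: no imaging formats, no
preprocessing — the activity matrix is the input.

## What it computes

1. **Behavior.** Old-item test trials from the branching source-memory probe
   (Q1 "seen before?", Q2 "remember the action?", Q3 two-alternative action
   choice) are classified into *source*, *item*, *incorrect source*, *miss*
   and *no response*, and each subject gets the guess-corrected source memory
   index

   `corrected = (n_source − n_incorrect_source) / n_old`,

   which is 0 in expectation when the two-alternative Q3 choice is at its
   0.5 chance level. Subjects with fewer than 6 trials in a condition of
   interest can be excluded.

2. **Trajectories.** Per ROI, activity is regressed on age with a penalized
   cubic regression spline (basis dimension 10, REML smoothness selection)
   plus sex, a single outlier pass removes observations with |residual| > 4
   SD and refits once, and the fitted curve and its central-difference
   derivative are evaluated on 100 equispaced ages. ROIs with no evidence of
   subsequent-memory activity (neither a nonzero mean contrast nor an age
   effect, under Benjamini–Hochberg FDR across ROIs) are set aside as
   "cluster 0".

3. **Clustering.** The dissimilarity between two ROIs is the least-squares
   sum of their derivative curves, `D[i,j] = Σ_g (d_i[g] − d_j[g])²` —
   derivatives rather than raw curves, so the grouping reflects trajectory
   shape and ignores each region's mean activity level. k-medoids (PAM with
   random-restart SWAP descents, fully deterministic) partitions the ROIs and
   the number of clusters is chosen by the average silhouette width.
   Stability checks: stratified half-split replication and removal of the
   10% highest-motion subjects, both scored by the adjusted Rand index.

4. **Associations.** Per cluster, subjects are scored by the first principal
   component of the cluster's activity submatrix, and scores are related to
   cognitive measures and grey-matter component loadings with
   `score ~ s(age) + s(covariate) + sex` GAMs (extra wiggliness penalty
   gamma = 2), under BH-FDR with an explicit family size.

5. **Topology.** Whether a cluster occupies distinctive territory on external
   brain-organization maps (flexibility, principal connectivity gradient,
   evolutionary expansion — the latter mid-rank-transformed because of its
   skewed marginal) is tested by permuting cluster labels over ROIs
   (10,000 permutations, two-sided, FDR-corrected).

6. **Synthetic data.** Because cohorts of this kind are rarely shareable, a
   generator produces every input with known ground truth: a cohort with
   U-shaped motion, an activity matrix built from five canonical trajectory
   shapes (monotonic increase, U-shape, weak and steep inverted-U,
   developmental rise-to-plateau) plus a null block, branching trial
   responses with an inverted-U performance profile, age-locked grey-matter
   components, and maps enriched in a chosen cluster. All downstream claims
   are validated against this planted truth.

## Worked example

```r
library(lifetraj)

study <- simulate_study(n = 300, n_rois = 120, noise_sd = 0.125, seed = 1)

scores <- score_subjects(study$trials)
head(scores[, c("subject_id", "n_source", "n_item",
                "n_incorrect_source", "n_miss", "corrected_index")], 3)
#>   subject_id n_source n_item n_incorrect_source n_miss corrected_index
#> 1    sub0001       19      7                 13      9            0.12
#> 2    sub0002       18      8                 11     12            0.14
#> 3    sub0003       16     13                  7     14            0.18

res <- run_pipeline(study$activity, study$cohort, k_range = 2:10)
res$solution
#> <cluster_solution> k = 6, avg silhouette = 0.903, objective = 0.04363
#> cluster
#>  1  2  3  4  5  6
#> 40 20 16 14 10  3

eff <- names(res$solution$assignment)
adjusted_rand_index(study$truth$assignment[eff], res$solution$assignment)
#> [1] 1
```

The five planted trajectory families are recovered exactly (clusters 1–5,
sizes 40/20/16/14/10; adjusted Rand index 1 against the planted labels).
The sixth, three-ROI cluster is instructive rather than a defect: the effect
flag controls the false discovery rate at 0.05, so a few genuinely null
regions whose noise happens to track age survive it, and their near-zero
derivative curves are more similar to each other than to any real trajectory
family. Silhouette then prefers giving them their own cluster (0.903 at k = 6
vs 0.879 at k = 5). On real data such a mini-cluster flags regions whose
membership deserves scrutiny.

```r
enr <- permutation_enrichment(study$maps, res$solution,
                              n_perm = 10000, seed = 20)
subset(enr, q < 0.05)
#>    cluster         map observed          p          q n_roi
#> 4        4 flexibility  1.19386 0.00019998 0.00179982    14
#> 16       4   expansion 36.60935 0.00009999 0.00179982    14
```

The generator planted a one-SD enrichment of cluster 4 (the steep inverted-U
cluster) in every map; the permutation test recovers it in flexibility and
(after rank-transform) expansion at q < 0.05.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full analysis from scratch against the installed package at the
given seed — simulating the reference study, scoring behavior, fitting and
clustering trajectories, testing associations and map enrichment — logging a
summary to stderr and writing the JSON report to `--out`.

## Vignette

`vignettes/lifespan-trajectory-clustering.Rmd` documents the model and every
tunable choice (spline basis, outlier rule, dissimilarity, cluster-count
selection, FDR families, permutation scheme), what the synthetic world does
and does not emulate, and known limitations.
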