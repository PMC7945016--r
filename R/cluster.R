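# Derivative-based clustering of ROI lifespan trajectories. Dissimilarity
# between two ROIs is the least-squares sum of their trajectory derivatives
# over the common age grid; working on derivatives removes the intercept
# (mean activity) so regions group by trajectory *shape* regardless of the
# sign or size of their memory effect. Partitioning is k-medoids (PAM,
# deterministic BUILD + SWAP) with the number of clusters chosen by the
# average silhouette width.

#' Build the derivative dissimilarity matrix
#'
#' `D[i, j] = sum_g (d_i[g] - d_j[g])^2` over the grid ages, computed for
#' effect-bearing ROIs only: ROIs flagged without subsequent-memory activity
#' ("cluster 0") are removed before the matrix is formed.
#'
#' @param derivs ROI x grid matrix of trajectory derivatives (rownames =
#'   ROI ids), or a `trajfit_set`.
#' @param flags optional output of [flag_memory_effect()]; if given, only
#'   ROIs with `has_effect` are retained.
#' @return symmetric matrix with zero diagonal, dimnames = retained ROI ids.
#' @examples
#' d <- rbind(a = c(0, 1, 2), b = c(1, 1, 1))
#' build_dissimilarity(d)  # D[a, b] = 1 + 0 + 1 = 2
#' @export
build_dissimilarity <- function(derivs, flags = NULL) {
  if (inherits(derivs, "trajfit_set")) derivs <- derivs$derivs
  stopifnot(is.matrix(derivs))
  if (!is.null(flags)) {
    keep <- flags$roi_id[flags$has_effect]
    missing <- setdiff(keep, rownames(derivs))
    if (length(missing)) stop_invalid("flags refer to unknown ROIs")
    derivs <- derivs[keep, , drop = FALSE]
  }
  if (anyNA(derivs)) stop_invalid("derivative vectors contain NA")
  D <- as.matrix(dist(derivs, method = "euclidean"))^2
  diag(D) <- 0
  D
}

check_diss <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop_invalid("D must be a square dissimilarity matrix")
  if (max(abs(D - t(D))) > 1e-8) stop_invalid("D must be symmetric")
  if (any(D < 0)) stop_invalid("dissimilarities must be nonnegative")
  invisible(D)
}

#' k-medoids partition of a dissimilarity matrix
#'
#' PAM (BUILD initialization followed by SWAP until no swap lowers the
#' objective) via [cluster::pam()], augmented with `nstart` random-restart
#' SWAP descents run under a locally fixed RNG seed; the best local optimum
#' by objective is returned, the BUILD solution winning ties. Plain
#' BUILD+SWAP lands in a non-global 1-swap optimum on roughly 8% of small
#' random instances, so restarts are needed for the solution to be
#' reproducibly the best attainable; the procedure remains fully
#' deterministic (the caller's RNG state is saved and restored). The
#' objective is the total dissimilarity of each point to its medoid.
#' Cluster labels are canonicalized by descending cluster size (the raw
#' numbering of a k-medoids run is arbitrary).
#'
#' @param D square symmetric dissimilarity matrix with dimnames.
#' @param k number of clusters, `2 <= k <= n`.
#' @param nstart number of random-restart descents besides BUILD
#'   (default 20; 0 gives classic deterministic BUILD+SWAP only).
#' @return object of class `cluster_solution`: list with `k`, `assignment`
#'   (named integer vector, labels 1..k), `medoids` (ROI ids, one per
#'   label), `silhouette` (per-ROI widths, named; `NA` when `k = n`),
#'   `avg_silhouette`, `objective`.
#' @export
pam_fit <- function(D, k, nstart = 20) {
  check_diss(D)
  n <- nrow(D)
  check_count(k, "k", min = 2)
  if (k > n) stop_invalid("k cannot exceed the number of ROIs")
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k == n) {
    assignment <- setNames(seq_len(n), ids)
    return(structure(list(k = n, assignment = assignment, medoids = ids,
                          silhouette = setNames(rep(NA_real_, n), ids),
                          avg_silhouette = NA_real_, objective = 0),
                     class = "cluster_solution"))
  }
  d <- as.dist(D)
  p <- cluster::pam(d, k = k, diss = TRUE, keep.diss = FALSE)
  subset_obj <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))
  if (nstart > 0 && k < n) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    set.seed(104729L)  # local, restored below: restarts are reproducible
    pr <- cluster::pam(d, k = k, diss = TRUE, keep.diss = FALSE,
                       medoids = "random", nstart = nstart)
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
    if (subset_obj(pr$id.med) < subset_obj(p$id.med) - 1e-12) p <- pr
  }
  assignment <- setNames(as.integer(p$clustering), ids)
  medoid_idx <- as.integer(p$id.med)
  # canonical labels: descending cluster size, ties by first occurrence
  sizes <- tabulate(assignment, nbins = k)
  relabel <- order(order(-sizes, seq_len(k)))
  assignment <- setNames(relabel[assignment], ids)
  medoids <- character(k)
  medoids[relabel] <- ids[medoid_idx]
  objective <- sum(D[cbind(seq_len(n),
                           match(medoids[assignment], ids))])
  sil <- silhouette_widths(D, assignment)
  structure(list(k = k, assignment = assignment, medoids = medoids,
                 silhouette = setNames(sil$sil_width, ids),
                 avg_silhouette = mean(sil$sil_width),
                 objective = objective),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, avg silhouette = %s, objective = %.4g\n",
              x$k,
              if (is.na(x$avg_silhouette)) "NA"
              else sprintf("%.3f", x$avg_silhouette),
              x$objective))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Silhouette widths on a precomputed dissimilarity matrix
#'
#' Standard silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a` is
#' the mean dissimilarity to the own cluster and `b` the smallest mean
#' dissimilarity to another cluster; singleton clusters score 0. Computed
#' with [cluster::silhouette()].
#'
#' @param D square symmetric dissimilarity matrix.
#' @param assignment integer cluster labels (>= 2 distinct, all nonempty),
#'   aligned with the rows of `D`.
#' @return data.frame `roi_id`, `cluster`, `neighbor`, `sil_width`.
#' @export
silhouette_widths <- function(D, assignment) {
  check_diss(D)
  if (length(assignment) != nrow(D))
    stop_invalid("assignment length must match D")
  if (length(unique(assignment)) < 2)
    stop_invalid("silhouettes require at least 2 clusters")
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(D)))
  s <- cluster::silhouette(as.integer(assignment), dmatrix = D)
  data.frame(roi_id = ids,
             cluster = as.integer(s[, "cluster"]),
             neighbor = as.integer(s[, "neighbor"]),
             sil_width = as.numeric(s[, "sil_width"]),
             stringsAsFactors = FALSE)
}

#' Choose the number of clusters by average silhouette
#'
#' Runs [pam_fit()] for each `k` in `k_range` and returns the solution with
#' the largest average silhouette width, together with the full silhouette
#' profile (so alternative local optima can be inspected).
#'
#' @param D dissimilarity matrix.
#' @param k_range candidate cluster counts (default 2:10).
#' @return list with `solution` (best `cluster_solution`) and `profile`
#'   (data.frame `k`, `avg_silhouette`).
#' @export
select_k <- function(D, k_range = 2:10) {
  check_diss(D)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range < nrow(D)]
  if (!length(k_range)) stop_invalid("k_range has no valid values")
  sols <- lapply(k_range, function(k) pam_fit(D, k))
  avg <- vapply(sols, function(s) s$avg_silhouette, numeric(1))
  best <- which.max(avg)  # ties: smallest k
  list(solution = sols[[best]],
       profile = data.frame(k = k_range, avg_silhouette = avg))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions (up to label
#' permutation), ~0 for independent ones.
#'
#' @param a,b cluster label vectors over the same objects.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("partitions differ in length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Run the full trajectory-clustering pipeline
#'
#' Fit all ROI trajectories (with the outlier refit pass), flag ROIs without
#' subsequent-memory activity, build the derivative dissimilarity matrix
#' over effect ROIs, and select the cluster solution by silhouette.
#'
#' @param activity subjects x ROIs matrix.
#' @param subjects data.frame with `age` (and optionally `sex`).
#' @param basis_dim,grid_n,sd_threshold see [fit_rois()].
#' @param alpha FDR level for the effect flag.
#' @param k_range candidate cluster counts.
#' @return list of class `lifespan_pipeline`: `fits` (`trajfit_set`),
#'   `flags`, `D`, `solution`, `profile`, and `assignment_full` (named
#'   labels over all ROIs with 0 for no-effect ROIs).
#' @examples
#' \donttest{
#' study <- simulate_study(n = 120, n_rois = 18,
#'   cluster_sizes = c(3, 3, 3, 3, 3, 3), seed = 1)
#' res <- run_pipeline(study$activity, study$cohort, k_range = 2:6)
#' res$solution$k
#' }
#' @export
run_pipeline <- function(activity, subjects, basis_dim = 10, grid_n = 100,
                         sd_threshold = 4, alpha = 0.05, k_range = 2:10) {
  fits <- fit_rois(activity, subjects, basis_dim = basis_dim,
                   grid_n = grid_n, sd_threshold = sd_threshold)
  flags <- flag_memory_effect(fits, alpha = alpha)
  D <- build_dissimilarity(fits, flags)
  sel <- select_k(D, k_range = k_range)
  assignment_full <- setNames(rep(0L, nrow(flags)), flags$roi_id)
  assignment_full[names(sel$solution$assignment)] <-
    sel$solution$assignment
  structure(list(fits = fits, flags = flags, D = D,
                 solution = sel$solution, profile = sel$profile,
                 assignment_full = assignment_full),
            class = "lifespan_pipeline")
}

#' @export
print.lifespan_pipeline <- function(x, ...) {
  cat(sprintf(
    "<lifespan_pipeline> %d ROIs (%d with memory effects), selected k = %d (avg silhouette %.3f)\n",
    nrow(x$flags), sum(x$flags$has_effect), x$solution$k,
    x$solution$avg_silhouette))
  invisible(x)
}

decile_strata <- function(subjects) {
  br <- unique(quantile(subjects$age, probs = seq(0, 1, 0.1)))
  dec <- cut(subjects$age, breaks = br, include.lowest = TRUE)
  if ("sex" %in% names(subjects)) interaction(dec, subjects$sex) else dec
}

#' Half-split replication of the cluster solution
#'
#' Randomly splits subjects into two halves (stratified by age decile and
#' sex), reruns the full pipeline in each half, and reports the adjusted
#' Rand agreement between the two assignments over ROIs flagged
#' effect-bearing in both halves.
#'
#' @param activity,subjects as in [run_pipeline()].
#' @param seed integer seed for the split.
#' @param halves optional list of two row-index vectors prescribing the
#'   split (overrides the stratified sampling; useful for sanity checks
#'   such as feeding identical halves).
#' @param ... passed to [run_pipeline()].
#' @return list with `half1`, `half2` (pipeline results), `ari`,
#'   `common_rois`, and the two index vectors `idx1`, `idx2`.
#' @export
half_split_replication <- function(activity, subjects, seed = NULL,
                                   halves = NULL, ...) {
  set_seed_if(seed)
  n <- nrow(subjects)
  if (is.null(halves)) {
    strata <- decile_strata(subjects)
    idx1 <- unlist(lapply(split(seq_len(n), strata), function(ix) {
      if (!length(ix)) return(integer(0))
      sample(ix, floor(length(ix) / 2))
    }), use.names = FALSE)
    idx2 <- setdiff(seq_len(n), idx1)
  } else {
    stopifnot(is.list(halves), length(halves) == 2)
    idx1 <- halves[[1]]
    idx2 <- halves[[2]]
  }
  half1 <- run_pipeline(activity[idx1, , drop = FALSE],
                        subjects[idx1, , drop = FALSE], ...)
  half2 <- run_pipeline(activity[idx2, , drop = FALSE],
                        subjects[idx2, , drop = FALSE], ...)
  common <- intersect(names(half1$solution$assignment),
                      names(half2$solution$assignment))
  ari <- if (length(common) > 1)
    adjusted_rand_index(half1$solution$assignment[common],
                        half2$solution$assignment[common])
  else NA_real_
  list(half1 = half1, half2 = half2, ari = ari, common_rois = common,
       idx1 = sort(idx1), idx2 = idx2)
}

#' Sensitivity of the solution to high-motion subjects
#'
#' Drops the `fraction` of subjects with the highest mean motion (DVARS-like
#' summary), reruns the pipeline, and reports adjusted Rand agreement with
#' the full-sample solution over ROIs flagged in both runs.
#'
#' @param activity,subjects as in [run_pipeline()]; `subjects$mean_motion`
#'   is required.
#' @param fraction fraction of subjects to remove (default 0.10); the count
#'   removed is `ceiling(fraction * n)`.
#' @param full optional precomputed full-sample pipeline result (recomputed
#'   when omitted).
#' @param ... passed to [run_pipeline()].
#' @return list with `full`, `reduced`, `ari`, `removed` (subject ids).
#' @export
motion_sensitivity <- function(activity, subjects, fraction = 0.10,
                               full = NULL, ...) {
  if (!"mean_motion" %in% names(subjects))
    stop_invalid("subjects$mean_motion is required")
  check_number(fraction, "fraction", min = 0)
  if (fraction >= 1) stop_invalid("fraction must be < 1")
  if (is.null(full)) full <- run_pipeline(activity, subjects, ...)
  n_drop <- ceiling(fraction * nrow(subjects))
  if (n_drop == 0) {
    return(list(full = full, reduced = full, ari = 1,
                removed = character(0)))
  }
  drop_idx <- order(subjects$mean_motion, decreasing = TRUE)[seq_len(n_drop)]
  reduced <- run_pipeline(activity[-drop_idx, , drop = FALSE],
                          subjects[-drop_idx, , drop = FALSE], ...)
  common <- intersect(names(full$solution$assignment),
                      names(reduced$solution$assignment))
  ari <- if (length(common) > 1)
    adjusted_rand_index(full$solution$assignment[common],
                        reduced$solution$assignment[common])
  else NA_real_
  list(full = full, reduced = reduced, ari = ari,
       removed = subjects$subject_id[drop_idx])
}
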