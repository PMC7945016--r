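# Enrichment of cluster membership in external brain-organization maps
# (flexibility, principal connectivity gradient, evolutionary expansion),
# tested against a label-permutation null.

#' Mid-rank transform of a brain map
#'
#' Replaces map values by their mid-ranks (ties share the mean rank),
#' preserving `NA`s. Used for maps with strongly skewed marginals (e.g.
#' evolutionary expansion, which is approximately exponential); any strictly
#' monotone re-expression of the input yields identical ranks, so enrichment
#' p-values become invariant to the map's scale.
#'
#' @param x numeric map values.
#' @return mid-ranks, same length; `NA` kept in place.
#' @examples
#' rank_transform(c(5, 5, 1))  # 2.5 2.5 1
#' @export
rank_transform <- function(x) {
  rank(x, ties.method = "average", na.last = "keep")
}

#' Permutation test of cluster enrichment in brain maps
#'
#' For each cluster and map, the observed statistic is the mean map value of
#' the cluster's ROIs minus the mean over all other (effect-bearing) ROIs.
#' The null distribution is built by randomly permuting cluster labels over
#' ROIs (preserving cluster sizes) and recomputing the statistic; the
#' two-sided p-value is `(1 + #{|null| >= |observed|}) / (n_perm + 1)`, so p
#' can never fall below `1/(n_perm + 1)`. Benjamini-Hochberg correction is
#' applied across the cluster x map family. ROIs with `NA` map values (e.g.
#' subcortical ROIs for surface-only maps) are dropped per map.
#'
#' @param maps data.frame with `roi_id` and one column per map, or a named
#'   numeric vector for a single map.
#' @param solution `cluster_solution` or named assignment vector (labels
#'   >= 1 are tested).
#' @param n_perm number of label permutations (default 10000; < 100 warns).
#' @param seed integer seed.
#' @param rank_maps map names to mid-rank before testing (default
#'   `"expansion"` when present).
#' @param family explicit FDR family size (default: rows of the result).
#' @return data.frame `cluster`, `map`, `observed`, `p`, `q`, `n_roi`.
#' @export
permutation_enrichment <- function(maps, solution, n_perm = 10000,
                                   seed = NULL, rank_maps = NULL,
                                   family = NULL) {
  check_count(n_perm, "n_perm", min = 1)
  if (n_perm < 100)
    warning("n_perm < 100 gives a very coarse permutation null")
  assignment <- if (inherits(solution, "cluster_solution"))
    solution$assignment else solution
  assignment <- assignment[assignment >= 1]
  if (length(unique(assignment)) < 2)
    stop_invalid("enrichment needs >= 2 clusters")
  if (is.numeric(maps)) {
    maps <- data.frame(roi_id = names(maps), map = unname(maps),
                       stringsAsFactors = FALSE)
  }
  stopifnot("roi_id" %in% names(maps))
  map_names <- setdiff(names(maps), "roi_id")
  if (is.null(rank_maps)) rank_maps <- intersect("expansion", map_names)
  set_seed_if(seed)
  rows <- list()
  for (mn in map_names) {
    v <- maps[[mn]][match(names(assignment), maps$roi_id)]
    ok <- !is.na(v)
    v_ok <- v[ok]
    if (mn %in% rank_maps) v_ok <- rank_transform(v_ok)
    lab <- assignment[ok]
    n <- length(v_ok)
    labs <- sort(unique(lab))
    # permuted map values, one row per permutation
    idx <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    V <- matrix(v_ok[idx], nrow = n_perm, ncol = n, byrow = TRUE)
    total <- sum(v_ok)
    for (cl in labs) {
      inc <- lab == cl
      n_in <- sum(inc)
      if (n_in == n) next
      obs <- mean(v_ok[inc]) - mean(v_ok[!inc])
      in_sum <- if (n_in == 1L) V[, inc] else rowSums(V[, inc, drop = FALSE])
      null_stat <- in_sum / n_in - (total - in_sum) / (n - n_in)
      p <- (1 + sum(abs(null_stat) >= abs(obs) - 1e-12)) / (n_perm + 1)
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = cl, map = mn, observed = obs, p = p,
                   n_roi = n_in, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(family)) family <- nrow(out)
  out$q <- fdr_correct(out$p, family = family)
  rownames(out) <- NULL
  out[, c("cluster", "map", "observed", "p", "q", "n_roi")]
}
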