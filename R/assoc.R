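# Subject-level cluster activity scores and their associations with
# cognition and grey-matter variation, controlling for age and sex.

#' PCA-based subject scores of cluster activity
#'
#' For each cluster, the subjects x ROIs submatrix is column-centered and
#' the projection on its first principal component is used as the subject's
#' encoding-activity score. Scores are centered by construction; the sign is
#' oriented so that the score correlates positively with the cluster's mean
#' ROI activity (higher score = stronger positive memory effect for
#' positive-effect clusters).
#'
#' @param activity subjects x ROIs matrix.
#' @param solution a `cluster_solution` (or a named assignment vector with
#'   labels >= 1; label 0 / no-effect ROIs are ignored).
#' @return data.frame `subject_id`, `cluster`, `score`, plus attribute
#'   `var_explained` (named by cluster).
#' @export
cluster_scores <- function(activity, solution) {
  assignment <- if (inherits(solution, "cluster_solution"))
    solution$assignment else solution
  assignment <- assignment[assignment >= 1]
  if (!length(assignment)) stop_invalid("no clustered ROIs in solution")
  if (!all(names(assignment) %in% colnames(activity)))
    stop_invalid("solution refers to ROIs absent from the activity matrix")
  subject_id <- rownames(activity)
  if (is.null(subject_id)) subject_id <- as.character(seq_len(nrow(activity)))
  labs <- sort(unique(assignment))
  out <- vector("list", length(labs))
  varexp <- setNames(numeric(length(labs)), labs)
  for (i in seq_along(labs)) {
    rois <- names(assignment)[assignment == labs[i]]
    X <- activity[, rois, drop = FALSE]
    Xc <- scale(X, center = TRUE, scale = FALSE)
    pc <- prcomp(Xc, center = FALSE, scale. = FALSE)
    score <- pc$x[, 1]
    cm <- rowMeans(X)
    if (ncol(X) == 1L || isTRUE(cor(score, cm) < 0)) {
      if (ncol(X) == 1L) score <- Xc[, 1] else score <- -score
    }
    varexp[i] <- pc$sdev[1]^2 / sum(pc$sdev^2)
    out[[i]] <- data.frame(subject_id = subject_id, cluster = labs[i],
                           score = as.numeric(score),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "var_explained") <- varexp
  res
}

#' GAM association between a cluster score and a covariate
#'
#' Additive model `score ~ s(age) + s(covariate) + sex` with an extra
#' wiggliness penalty (`gamma = 2`, REML smoothness selection), reporting
#' the approximate F test, p-value and estimated degrees of freedom of the
#' covariate smooth, i.e. the covariate's partial effect controlling for a
#' smooth age trend and sex.
#'
#' @param score numeric outcome (per-subject cluster activity score).
#' @param covariate numeric predictor (cognitive score or GM loading).
#' @param age years; `sex` optional factor.
#' @param sex optional factor covariate.
#' @param penalty_gamma extra smoothing-penalty multiplier (default 2).
#' @param basis_dim basis dimension of both smooths (default 10).
#' @return one-row data.frame `F`, `p`, `edf`.
#' @export
gam_association <- function(score, covariate, age, sex = NULL,
                            penalty_gamma = 2, basis_dim = 10) {
  if (length(unique(covariate)) < 2)
    stop_invalid("covariate is constant")
  n_ok <- sum(stats::complete.cases(score, covariate, age))
  if (n_ok < 50) stop_invalid("need >= 50 complete cases")
  dat <- data.frame(score = score, covariate = covariate, age = age)
  has_sex <- !is.null(sex)
  if (has_sex) {
    dat$sex <- factor(sex)
    if (nlevels(dat$sex) < 2) has_sex <- FALSE
  }
  fml <- if (has_sex)
    score ~ s(age, k = basis_dim, bs = "cr") +
      s(covariate, k = basis_dim, bs = "cr") + sex
  else
    score ~ s(age, k = basis_dim, bs = "cr") +
      s(covariate, k = basis_dim, bs = "cr")
  m <- mgcv::gam(fml, data = dat, method = "REML", gamma = penalty_gamma)
  st <- summary(m)$s.table
  data.frame(F = unname(st["s(covariate)", "F"]),
             p = min(max(st["s(covariate)", "p-value"],
                         .Machine$double.xmin), 1),
             edf = unname(st["s(covariate)", "edf"]))
}

#' Benjamini-Hochberg FDR adjustment with an explicit family size
#'
#' Step-up adjusted p-values controlling the false discovery rate under
#' positive dependence. The family size is an explicit argument (reported
#' families may be larger than the p-values at hand, e.g. when a family
#' spans clusters x covariates tested in separate calls).
#'
#' @param p p-values in (0, 1].
#' @param family family size (>= `length(p)`; default `length(p)`).
#' @return adjusted q-values, same length and order as `p`.
#' @examples
#' fdr_correct(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdr_correct <- function(p, family = length(p)) {
  if (!is.numeric(p) || !length(p) || any(is.na(p)) ||
      any(p <= 0 | p > 1))
    stop_invalid("p-values must lie in (0, 1]")
  check_count(family, "family", min = 1)
  if (family < length(p)) stop_invalid("family cannot be smaller than length(p)")
  p.adjust(p, method = "BH", n = family)
}

#' Cluster-by-covariate association table with FDR correction
#'
#' Runs [gam_association()] for every cluster score against every covariate
#' column and applies Benjamini-Hochberg correction across the whole family
#' (explicit `family` size, defaulting to clusters x covariates).
#'
#' @param scores output of [cluster_scores()].
#' @param covariates data.frame with `subject_id` and covariate columns.
#' @param subjects data.frame with `subject_id`, `age`, optional `sex`.
#' @param covariate_names columns of `covariates` to test (default: all
#'   non-id columns).
#' @param family explicit FDR family size.
#' @param ... passed to [gam_association()].
#' @return data.frame `cluster`, `covariate`, `F`, `p`, `q`, `edf`,
#'   `family`.
#' @export
associate_clusters <- function(scores, covariates, subjects,
                               covariate_names = NULL, family = NULL, ...) {
  if (is.null(covariate_names))
    covariate_names <- setdiff(names(covariates), "subject_id")
  labs <- sort(unique(scores$cluster))
  rows <- list()
  for (cl in labs) {
    sc <- scores[scores$cluster == cl, ]
    m <- match(sc$subject_id, subjects$subject_id)
    mc <- match(sc$subject_id, covariates$subject_id)
    for (cv in covariate_names) {
      res <- gam_association(sc$score, covariates[[cv]][mc],
                             subjects$age[m],
                             sex = if ("sex" %in% names(subjects))
                               subjects$sex[m], ...)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(cluster = cl, covariate = cv,
                         stringsAsFactors = FALSE), res)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(family)) family <- nrow(out)
  out$q <- fdr_correct(out$p, family = family)
  out$family <- family
  rownames(out) <- NULL
  out
}
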