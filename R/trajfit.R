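# Per-ROI lifespan trajectory fitting. Each ROI's encoding-activity values
# are regressed on age with a penalized cubic regression spline (basis
# dimension 10, REML smoothness selection) and sex as an additive covariate.
# The fitted curve is evaluated on a 100-point equispaced age grid and its
# derivative taken by central finite differences; a single outlier-removal
# pass (|residual| > 4 SD) refits the model once.

#' Numerical derivative on an equispaced grid
#'
#' Central finite differences at interior points, one-sided differences at
#' the two endpoints. Exact for quadratics at interior points.
#'
#' @param values function values on the grid.
#' @param x grid locations (equispaced, length >= 3).
#' @return derivative values, same length as `values`.
#' @examples
#' x <- seq(0, 1, length.out = 100)
#' max(abs(grid_derivative(x^2, x)[2:99] - 2 * x[2:99]))
#' @export
grid_derivative <- function(values, x) {
  n <- length(values)
  if (length(x) != n || n < 3) stop_invalid("need >= 3 grid points")
  h <- diff(x)
  if (max(h) - min(h) > 1e-8 * mean(h)) stop_invalid("grid must be equispaced")
  h <- mean(h)
  d <- numeric(n)
  d[1] <- (values[2] - values[1]) / h
  d[n] <- (values[n] - values[n - 1]) / h
  d[2:(n - 1)] <- (values[3:n] - values[1:(n - 2)]) / (2 * h)
  d
}

gam_formula <- function(basis_dim, has_sex) {
  if (has_sex) y ~ s(age, k = basis_dim, bs = "cr") + sex
  else y ~ s(age, k = basis_dim, bs = "cr")
}

#' Fit one ROI's lifespan activity trajectory
#'
#' Penalized-spline GAM of activity on age (cubic regression spline, basis
#' dimension `basis_dim`, smoothing parameter by REML) with sex as an
#' additive covariate. The fitted curve (at the reference sex) and its
#' central-difference derivative are returned on `grid_n` equispaced ages
#' spanning the observed age range, together with the model intercept
#' ("mean activity"), the approximate F test of the age smooth, its
#' estimated degrees of freedom (edf), and the intercept test used by
#' [flag_memory_effect()].
#'
#' @param activity numeric vector of per-subject contrast values (percent
#'   signal change).
#' @param age ages in years (no missing values, non-constant).
#' @param sex factor (or coercible) with up to two levels; may be omitted.
#' @param basis_dim spline basis dimension (default 10).
#' @param grid_n number of equispaced grid ages (default 100).
#' @param roi_id identifier carried through to outputs.
#' @param grid optional explicit age grid overriding `grid_n` (used when a
#'   refit must be evaluated on the original sample's grid).
#' @return object of class `roi_fit`: list with `roi_id`, `grid`, `fitted`,
#'   `derivative`, `mean_activity`, `mean_p`, `age_F`, `age_p`, `edf`,
#'   `n_outliers_removed`, `residuals`, `n`.
#' @examples
#' set.seed(1)
#' age <- runif(200, 6, 82)
#' y <- 0.02 * age + rnorm(200, 0, 0.1)
#' f <- fit_roi(y, age)
#' round(f$edf, 1)
#' @export
fit_roi <- function(activity, age, sex = NULL, basis_dim = 10,
                    grid_n = 100, roi_id = NA_character_, grid = NULL) {
  check_count(basis_dim, "basis_dim", min = 3)
  check_count(grid_n, "grid_n", min = 3)
  if (anyNA(age) || anyNA(activity))
    stop_invalid("missing activity or age values are not allowed")
  if (length(activity) != length(age))
    stop_invalid("activity and age lengths differ")
  if (var(age) == 0) stop_invalid("age is constant: design is rank-deficient")
  if (length(activity) < 3 * basis_dim)
    stop_invalid("need at least 3 x basis_dim subjects")
  has_sex <- !is.null(sex)
  dat <- data.frame(y = activity, age = age)
  if (has_sex) {
    dat$sex <- factor(sex)
    if (nlevels(dat$sex) < 2) has_sex <- FALSE
  }
  m <- mgcv::gam(gam_formula(basis_dim, has_sex), data = dat,
                 method = "REML")
  smry <- summary(m)
  if (is.null(grid)) grid <- seq(min(age), max(age), length.out = grid_n)
  nd <- data.frame(age = grid)
  if (has_sex) nd$sex <- factor(levels(dat$sex)[1], levels = levels(dat$sex))
  fitted_grid <- as.numeric(predict(m, newdata = nd))
  age_p <- max(smry$s.table["s(age)", "p-value"], .Machine$double.xmin)
  structure(list(
    roi_id = roi_id,
    grid = grid,
    fitted = fitted_grid,
    derivative = grid_derivative(fitted_grid, grid),
    mean_activity = unname(coef(m)[1]),
    mean_p = unname(smry$p.table["(Intercept)", "Pr(>|t|)"]),
    age_F = unname(smry$s.table["s(age)", "F"]),
    age_p = min(age_p, 1),
    edf = unname(smry$s.table["s(age)", "edf"]),
    n_outliers_removed = 0L,
    residuals = unname(residuals(m)),
    n = nrow(dat)
  ), class = "roi_fit")
}

#' @export
print.roi_fit <- function(x, ...) {
  cat(sprintf(
    "<roi_fit> %s: n = %d, edf = %.2f, age F = %.2f (p = %.3g), mean = %.3f, outliers removed = %d\n",
    x$roi_id, x$n, x$edf, x$age_F, x$age_p, x$mean_activity,
    x$n_outliers_removed))
  invisible(x)
}

#' Refit a trajectory after removing outlier observations
#'
#' Single-pass rule: observations whose residuals from the initial fit
#' exceed `sd_threshold` residual standard deviations in absolute value are
#' dropped and the model is refit once. With no flagged observations the
#' original fit is returned unchanged (so `sd_threshold = Inf` is a no-op).
#'
#' @param fit an initial [fit_roi()] result.
#' @param activity,age,sex the data the fit was computed from.
#' @param sd_threshold outlier threshold in residual SDs (default 4).
#' @param basis_dim,grid_n as in [fit_roi()].
#' @return an updated `roi_fit` with `n_outliers_removed` set.
#' @export
refit_without_outliers <- function(fit, activity, age, sex = NULL,
                                   sd_threshold = 4, basis_dim = 10,
                                   grid_n = 100) {
  stopifnot(inherits(fit, "roi_fit"))
  check_number(sd_threshold, "sd_threshold", min = 0)
  r <- fit$residuals
  if (length(r) != length(activity))
    stop_invalid("fit residuals do not match the supplied data")
  keep <- abs(r) <= sd_threshold * sd(r)
  if (!any(keep)) stop_invalid("all observations flagged as outliers")
  if (all(keep)) return(fit)
  # the refit keeps the full-sample grid so curves stay comparable
  refit <- fit_roi(activity[keep], age[keep],
                   sex = if (!is.null(sex)) sex[keep],
                   basis_dim = basis_dim, grid_n = grid_n,
                   roi_id = fit$roi_id, grid = fit$grid)
  refit$n_outliers_removed <- sum(!keep)
  refit
}

#' Fit trajectories for every ROI of an activity matrix
#'
#' Runs [fit_roi()] plus one [refit_without_outliers()] pass per ROI column
#' and collects curves and derivatives on the shared age grid.
#'
#' @param activity subjects x ROIs numeric matrix (column names = ROI ids).
#' @param subjects data.frame with `age` and optionally `sex`, rows aligned
#'   with `activity`.
#' @param basis_dim,grid_n,sd_threshold see [fit_roi()] and
#'   [refit_without_outliers()]; `sd_threshold = Inf` disables the outlier
#'   pass.
#' @return list of class `trajfit_set`: `summary` (data.frame of per-ROI
#'   statistics), `curves` and `derivs` (ROI x grid matrices), `grid`.
#' @export
fit_rois <- function(activity, subjects, basis_dim = 10, grid_n = 100,
                     sd_threshold = 4) {
  stopifnot(is.matrix(activity), nrow(activity) == nrow(subjects))
  roi_ids <- colnames(activity)
  if (is.null(roi_ids)) roi_ids <- sprintf("roi%03d", seq_len(ncol(activity)))
  sex <- if ("sex" %in% names(subjects)) subjects$sex
  grid <- seq(min(subjects$age), max(subjects$age), length.out = grid_n)
  curves <- derivs <- matrix(NA_real_, ncol(activity), grid_n,
                             dimnames = list(roi_ids, NULL))
  rows <- vector("list", ncol(activity))
  for (j in seq_along(roi_ids)) {
    f <- fit_roi(activity[, j], subjects$age, sex, basis_dim = basis_dim,
                 grid_n = grid_n, roi_id = roi_ids[j])
    if (is.finite(sd_threshold))
      f <- refit_without_outliers(f, activity[, j], subjects$age, sex,
                                  sd_threshold = sd_threshold,
                                  basis_dim = basis_dim, grid_n = grid_n)
    curves[j, ] <- f$fitted
    derivs[j, ] <- f$derivative
    rows[[j]] <- data.frame(roi_id = roi_ids[j],
                            mean_activity = f$mean_activity,
                            mean_p = f$mean_p, age_F = f$age_F,
                            age_p = f$age_p, edf = f$edf,
                            n_outliers_removed = f$n_outliers_removed,
                            stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, rows), curves = curves,
                 derivs = derivs, grid = grid),
            class = "trajfit_set")
}

#' @export
print.trajfit_set <- function(x, ...) {
  cat(sprintf("<trajfit_set> %d ROIs on a %d-point age grid [%.1f, %.1f]\n",
              nrow(x$summary), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Flag ROIs with evidence of subsequent-memory activity
#'
#' An ROI carries a subsequent-memory effect if either its mean contrast
#' differs from zero (intercept test of the age/sex-adjusted model) or its
#' age smooth is significant, each assessed under Benjamini-Hochberg FDR
#' across the ROI family. ROIs failing both are assigned "cluster 0" and
#' excluded from the dissimilarity matrix downstream.
#'
#' @param fits a `trajfit_set` from [fit_rois()] (or its `summary`).
#' @param alpha FDR level (default 0.05).
#' @return data.frame `roi_id`, `mean_p`, `age_p`, `mean_q`, `age_q`,
#'   `effect_p`, `effect_q`, `has_effect`.
#' @export
flag_memory_effect <- function(fits, alpha = 0.05) {
  smry <- if (inherits(fits, "trajfit_set")) fits$summary else fits
  stopifnot(all(c("roi_id", "mean_p", "age_p") %in% names(smry)))
  check_number(alpha, "alpha", min = 0)
  mean_q <- fdr_correct(pmax(smry$mean_p, .Machine$double.xmin))
  age_q <- fdr_correct(pmax(smry$age_p, .Machine$double.xmin))
  effect_q <- pmin(mean_q, age_q)
  effect_p <- ifelse(mean_q <= age_q, smry$mean_p, smry$age_p)
  data.frame(roi_id = smry$roi_id, mean_p = smry$mean_p,
             age_p = smry$age_p, mean_q = mean_q, age_q = age_q,
             effect_p = effect_p, effect_q = effect_q,
             has_effect = effect_q < alpha,
             stringsAsFactors = FALSE)
}
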