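# Synthetic-data generators. Every downstream stage of the package can be
# exercised against these with known ground truth; defaults emulate the
# statistical structure of a lifespan task-fMRI cohort (ages 6-82, inverted-U
# memory performance, five planted activity-trajectory families plus null
# regions, age-locked grey-matter components, maps enriched in one cluster).

#' Generate a synthetic lifespan cohort
#'
#' Draws a cohort of subjects with age, sex and a DVARS-like head-motion
#' summary. Ages are uniform on `[age_min, age_max]` by default (the real
#' cohort's age distribution is not public, so uniform is a neutral choice);
#' sexes are balanced in expectation; mean motion follows a U-shaped age
#' trajectory with a steeper limb in childhood than in older age, as in-scanner
#' motion does empirically.
#'
#' @param n number of subjects (>= 2).
#' @param age_min,age_max age range in years, `age_min < age_max`.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param p_female probability a subject is female.
#' @return a data.frame with columns `subject_id`, `age`, `sex`
#'   (factor female/male), `mean_motion` (nonnegative).
#' @examples
#' coh <- generate_cohort(100, seed = 1)
#' range(coh$age)
#' @export
generate_cohort <- function(n, age_min = 6, age_max = 82, seed = NULL,
                            p_female = 0.5) {
  check_count(n, "n", min = 2)
  if (!is.numeric(age_min) || !is.numeric(age_max) || age_min >= age_max)
    stop_invalid("age range must satisfy age_min < age_max")
  set_seed_if(seed)
  age <- runif(n, age_min, age_max)
  sex <- factor(ifelse(runif(n) < p_female, "female", "male"),
                levels = c("female", "male"))
  a <- normalize_age(age, age_min, age_max)
  # U-shape with a steeper childhood limb; lognormal noise keeps motion >= 0
  mu <- 0.25 + 2.5 * pmax(0, 0.35 - a)^2 + 0.25 * pmax(0, a - 0.35)^2
  mean_motion <- mu * rlnorm(n, 0, 0.25)
  data.frame(subject_id = sprintf("sub%04d", seq_len(n)),
             age = age, sex = sex, mean_motion = mean_motion,
             stringsAsFactors = FALSE)
}

#' Planted ground truth for the activity generator
#'
#' Assigns each ROI to one of five canonical trajectory clusters or to the
#' null block (cluster 0: no subsequent-memory effect), and fixes the shape,
#' amplitude, baseline and noise level used to generate activity. Default
#' cluster sizes (20 null / 40 / 20 / 16 / 14 / 10 over 120 ROIs) roughly
#' mirror the relative sizes reported for a 416-ROI solution
#' (74/212/50/47/20/13) at desk scale.
#'
#' @param n_rois total number of ROIs.
#' @param cluster_sizes integer vector: number of ROIs in cluster 0 (null)
#'   then clusters 1..5; must sum to `n_rois`.
#' @param shapes named list of `shape_spec` for clusters 1..5 (and "0" null).
#' @param noise_sd residual SD of activity values, activity units. Default
#'   0.125 = 0.25 x the steep-shape amplitude (0.5).
#' @return an object of class `ground_truth`: list with `roi_ids`,
#'   `assignment` (named integer, 0 = null), `shapes`, `noise_sd`.
#' @export
ground_truth <- function(n_rois = 120,
                         cluster_sizes = NULL,
                         shapes = NULL,
                         noise_sd = 0.125) {
  check_count(n_rois, "n_rois", min = 1)
  check_number(noise_sd, "noise_sd", min = 0)
  if (is.null(shapes)) {
    shapes <- list(
      "0" = shape_spec("null"),
      "1" = shape_spec("monotonic_up", amplitude = 0.5, baseline = -0.10),
      "2" = shape_spec("u_shape", amplitude = 0.5, baseline = -0.45),
      "3" = shape_spec("weak_inverted_u", amplitude = 0.5, baseline = 0.05),
      "4" = shape_spec("steep_inverted_u", amplitude = 0.5, baseline = 0.05),
      "5" = shape_spec("developmental_plateau", amplitude = 0.4, baseline = 0)
    )
  }
  if (is.null(cluster_sizes)) {
    k <- length(shapes) - 1L
    if (n_rois == 120 && k == 5L) {
      cluster_sizes <- c(20L, 40L, 20L, 16L, 14L, 10L)
    } else {
      base <- n_rois %/% (k + 1L)
      cluster_sizes <- rep(base, k + 1L)
      cluster_sizes[1L] <- n_rois - sum(cluster_sizes[-1L])
    }
  }
  if (sum(cluster_sizes) != n_rois)
    stop_invalid("cluster_sizes must sum to n_rois")
  if (length(cluster_sizes) != length(shapes))
    stop_invalid("need one size per shape (cluster 0 first)")
  labels <- as.integer(names(shapes))
  assignment <- rep(labels, times = cluster_sizes)
  roi_ids <- sprintf("roi%03d", seq_len(n_rois))
  names(assignment) <- roi_ids
  structure(list(roi_ids = roi_ids, assignment = assignment,
                 shapes = shapes, noise_sd = noise_sd),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d ROIs, noise_sd = %g\n",
              length(x$roi_ids), x$noise_sd))
  print(table(planted = x$assignment))
  invisible(x)
}

#' Generate a subjects-by-ROIs encoding-activity matrix
#'
#' Each cell is the planted cluster's canonical curve evaluated at the
#' subject's normalized age, plus the cluster baseline and independent
#' Gaussian noise. Null-cluster ROIs are pure zero-mean noise. Also builds an
#' ROI table with hemisphere and a cortical/subcortical flag (the trailing
#' ROIs of cluster 1 play the role of subcortex, as in an aseg-style
#' parcellation where only some external maps cover subcortex).
#'
#' @param cohort a cohort data.frame from [generate_cohort()].
#' @param truth a [ground_truth()] object.
#' @param seed integer seed.
#' @param n_subcortical number of ROIs flagged subcortical.
#' @return list with `activity` (numeric matrix, subjects x ROIs, dimnames
#'   set), `rois` (data.frame `roi_id`, `hemisphere`, `cortical`), and the
#'   `truth` used.
#' @examples
#' coh <- generate_cohort(50, seed = 1)
#' tr <- ground_truth(n_rois = 12, cluster_sizes = c(2, 2, 2, 2, 2, 2))
#' act <- generate_activity(coh, tr, seed = 2)
#' dim(act$activity)
#' @export
generate_activity <- function(cohort, truth, seed = NULL, n_subcortical = 8L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  n <- nrow(cohort)
  n_rois <- length(truth$roi_ids)
  if (n_rois < length(truth$shapes) - 1L)
    stop_invalid("need at least as many ROIs as planted clusters")
  set_seed_if(seed)
  a <- normalize_age(cohort$age)
  activity <- matrix(0, n, n_rois,
                     dimnames = list(cohort$subject_id, truth$roi_ids))
  for (j in seq_len(n_rois)) {
    spec <- truth$shapes[[as.character(truth$assignment[j])]]
    activity[, j] <- eval_shape(spec, a) + rnorm(n, 0, truth$noise_sd)
  }
  cluster1 <- which(truth$assignment == 1L)
  sub_idx <- tail(cluster1, min(n_subcortical, length(cluster1)))
  rois <- data.frame(
    roi_id = truth$roi_ids,
    hemisphere = rep_len(c("lh", "rh"), n_rois),
    cortical = !(seq_len(n_rois) %in% sub_idx),
    stringsAsFactors = FALSE
  )
  list(activity = activity, rois = rois, truth = truth)
}

#' Generate old-item memory-test trials
#'
#' Emulates the branching source-memory test for the old items of an
#' incidental encoding task: Q1 "seen before?" (yes/no), if yes Q2 "remember
#' the action?" (yes/no), if yes Q3 a two-alternative forced choice of the
#' encoding action (correct/incorrect). The age-dependent signal
#' `s(age) = eval_shape(perf_curve, a)` (clamped to `[0,1]`) drives all three
#' stages: `P(yes|Q1) = P(yes|Q2) = 0.5 + 0.5 s` and
#' `P(correct|Q3) = 0.5 + 0.5 s`, so Q3 is at the 0.5 chance level when the
#' signal is 0 and the expected guess-corrected index rises from 0 to 1 as the
#' signal goes from 0 to 1. A small non-response rate at Q1 yields
#' `no_response` trials.
#'
#' @param cohort cohort data.frame.
#' @param n_old old-item trials per subject (>= 6; the task presents 50).
#' @param perf_curve a `shape_spec` for the lifespan performance signal;
#'   default a steep inverted-U with amplitude 0.55 and baseline 0.05,
#'   giving the inverted-U source-memory performance profile.
#' @param seed integer seed.
#' @param p_no_response probability of no response at Q1.
#' @return data.frame `subject_id`, `trial`, `is_old`, `q1`, `q2`, `q3`
#'   (character; `NA` where the branch was not reached).
#' @export
generate_trials <- function(cohort, n_old = 50,
                            perf_curve = shape_spec("steep_inverted_u",
                                                    amplitude = 0.55,
                                                    baseline = 0.05),
                            seed = NULL, p_no_response = 0.02) {
  check_count(n_old, "n_old", min = 6)
  stopifnot(inherits(perf_curve, "shape_spec"))
  set_seed_if(seed)
  a <- normalize_age(cohort$age)
  s <- pmin(pmax(eval_shape(perf_curve, a), 0), 1)
  n <- nrow(cohort)
  total <- n * n_old
  sig <- rep(s, each = n_old)
  q1 <- ifelse(runif(total) < p_no_response, NA_character_,
               ifelse(runif(total) < 0.5 + 0.5 * sig, "yes", "no"))
  q2 <- ifelse(!is.na(q1) & q1 == "yes",
               ifelse(runif(total) < 0.5 + 0.5 * sig, "yes", "no"),
               NA_character_)
  q3 <- ifelse(!is.na(q2) & q2 == "yes",
               ifelse(runif(total) < 0.5 + 0.5 * sig, "correct", "incorrect"),
               NA_character_)
  data.frame(subject_id = rep(cohort$subject_id, each = n_old),
             trial = rep(seq_len(n_old), times = n),
             is_old = TRUE,
             q1 = q1, q2 = q2, q3 = q3,
             stringsAsFactors = FALSE)
}

#' Generate ROI-level brain-organization maps
#'
#' Builds three external maps over the ROIs: a flexibility-like and a
#' connectivity-gradient-like map (standard normal marginals) and an
#' evolutionary-expansion-like map with an exponential (positively skewed)
#' marginal, motivating the rank transform applied before enrichment testing.
#' Each map is shifted by `effect` in the ROIs of `enriched_cluster`.
#' If an ROI table is supplied, gradient and expansion values are `NA` for
#' subcortical ROIs (surface-based maps do not cover subcortex).
#'
#' @param truth a [ground_truth()] object.
#' @param enriched_cluster planted cluster label whose ROIs get the shift.
#' @param effect additive shift, in map SD units.
#' @param seed integer seed.
#' @param rois optional ROI table (from [generate_activity()]).
#' @return data.frame `roi_id`, `flexibility`, `gradient`, `expansion`.
#' @export
generate_maps <- function(truth, enriched_cluster = 4L, effect = 1,
                          seed = NULL, rois = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!enriched_cluster %in% truth$assignment)
    stop_invalid("enriched_cluster not present in truth")
  set_seed_if(seed)
  n <- length(truth$roi_ids)
  ind <- as.numeric(truth$assignment == enriched_cluster)
  maps <- data.frame(
    roi_id = truth$roi_ids,
    flexibility = rnorm(n) + effect * ind,
    gradient = rnorm(n) + effect * ind,
    expansion = rexp(n) + effect * ind,
    stringsAsFactors = FALSE
  )
  if (!is.null(rois)) {
    subcort <- !rois$cortical[match(maps$roi_id, rois$roi_id)]
    maps$gradient[subcort] <- NA_real_
    maps$expansion[subcort] <- NA_real_
  }
  maps
}

#' Generate cognitive scores and grey-matter component loadings
#'
#' Produces four cognitive scores with lifespan shapes (task source memory,
#' verbal learning and matrix reasoning as inverted-U "fluid-like" curves;
#' vocabulary as a developmental rise to a plateau, "crystallized-like") and
#' two grey-matter components: a dominant monotone-decreasing mode (age
#' explains `age_r2[1]`, default 0.86, of its variance) and an inverted-U
#' mode (`age_r2[2]`, default 0.46). Any score can additionally be coupled to
#' a planted cluster's mean activity at a target partial correlation given
#' age, to plant a detectable activity-cognition association.
#'
#' @param cohort cohort data.frame.
#' @param seed integer seed.
#' @param age_r2 length-2 numeric in (0,1): target age R-squared of the two
#'   GM components.
#' @param coupling optional list `list(score=, cluster=, partial_r=)` naming
#'   a generated column, a planted cluster and a target partial correlation.
#' @param activity,truth required when `coupling` is given: the activity
#'   matrix and ground truth used to form the coupled cluster's mean
#'   activity.
#' @return data.frame `subject_id`, `task_memory`, `cvlt_learning`,
#'   `matrices`, `vocabulary`, `gm_ic1`, `gm_ic2`.
#' @export
generate_covariates <- function(cohort, seed = NULL,
                                age_r2 = c(0.86, 0.46),
                                coupling = NULL,
                                activity = NULL, truth = NULL) {
  stopifnot(length(age_r2) == 2, all(age_r2 > 0 & age_r2 < 1))
  set_seed_if(seed)
  n <- nrow(cohort)
  a <- normalize_age(cohort$age)
  std <- function(x) as.numeric(scale(x))
  mix <- function(signal, r2) {
    sqrt(r2) * std(signal) + sqrt(1 - r2) * rnorm(n)
  }
  out <- data.frame(
    subject_id = cohort$subject_id,
    task_memory = mix(canonical_curve("steep_inverted_u", a), 0.30),
    cvlt_learning = mix(canonical_curve("steep_inverted_u", a)
                        - 0.3 * a, 0.30),
    matrices = mix(canonical_curve("steep_inverted_u", a), 0.35),
    vocabulary = mix(canonical_curve("developmental_plateau", a), 0.40),
    gm_ic1 = mix(-a, age_r2[1]),
    gm_ic2 = mix(canonical_curve("steep_inverted_u", a), age_r2[2]),
    stringsAsFactors = FALSE
  )
  if (!is.null(coupling)) {
    if (is.null(activity) || is.null(truth))
      stop_invalid("coupling requires activity and truth")
    stopifnot(coupling$score %in% names(out))
    rois <- names(truth$assignment)[truth$assignment == coupling$cluster]
    if (!length(rois)) stop_invalid("coupled cluster has no ROIs")
    clmean <- rowMeans(activity[cohort$subject_id, rois, drop = FALSE])
    z <- std(resid(mgcv::gam(clmean ~ s(age, k = 8), method = "REML",
                             data = data.frame(clmean = clmean,
                                               age = cohort$age))))
    r <- coupling$partial_r
    stopifnot(abs(r) < 1)
    base <- out[[coupling$score]]
    # replace the noise part with r*z + sqrt(1-r^2)*noise at matched scale
    out[[coupling$score]] <- base + r / sqrt(1 - r^2) * z
  }
  out
}

#' Simulate a complete synthetic study
#'
#' One-stop generator: cohort, planted ground truth, activity matrix, trial
#' table, brain maps and covariates, each with a sub-seed derived from
#' `seed`. This is the package's reference "stated world" for end-to-end
#' validation.
#'
#' @param n subjects; `n_rois` ROIs (see [ground_truth()] for defaults).
#' @param n_rois number of ROIs.
#' @param noise_sd activity noise SD.
#' @param seed master integer seed.
#' @param enriched_cluster,map_effect passed to [generate_maps()].
#' @param coupling passed to [generate_covariates()].
#' @return list with `cohort`, `truth`, `activity`, `rois`, `trials`,
#'   `maps`, `covariates`.
#' @examples
#' \donttest{
#' study <- simulate_study(n = 80, n_rois = 24,
#'   cluster_sizes = c(4, 4, 4, 4, 4, 4), seed = 1)
#' str(study$activity)
#' }
#' @param cluster_sizes passed to [ground_truth()].
#' @export
simulate_study <- function(n = 300, n_rois = 120, noise_sd = 0.125,
                           seed = 1, cluster_sizes = NULL,
                           enriched_cluster = 4L, map_effect = 1,
                           coupling = NULL) {
  check_count(seed, "seed", min = 0)
  sub_seed <- function(i) (seed * 7L + i) %% 2147483647L
  cohort <- generate_cohort(n, seed = sub_seed(1))
  truth <- ground_truth(n_rois = n_rois, cluster_sizes = cluster_sizes,
                        noise_sd = noise_sd)
  act <- generate_activity(cohort, truth, seed = sub_seed(2))
  trials <- generate_trials(cohort, seed = sub_seed(3))
  maps <- generate_maps(truth, enriched_cluster = enriched_cluster,
                        effect = map_effect, seed = sub_seed(4),
                        rois = act$rois)
  covariates <- generate_covariates(cohort, seed = sub_seed(5),
                                    coupling = coupling,
                                    activity = act$activity, truth = truth)
  list(cohort = cohort, truth = truth, activity = act$activity,
       rois = act$rois, trials = trials, maps = maps,
       covariates = covariates)
}

#' Write a simulated study to plain CSV/JSON files
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write.csv(study$cohort, p("subjects.csv"), row.names = FALSE)
  act <- data.frame(subject_id = rownames(study$activity),
                    study$activity, check.names = FALSE)
  write.csv(act, p("activity.csv"), row.names = FALSE)
  write.csv(study$trials, p("trials.csv"), row.names = FALSE)
  write.csv(study$maps, p("maps.csv"), row.names = FALSE)
  write.csv(study$covariates, p("covariates.csv"), row.names = FALSE)
  write.csv(study$rois, p("rois.csv"), row.names = FALSE)
  truth <- study$truth
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(assignment = as.list(truth$assignment),
           noise_sd = truth$noise_sd,
           shapes = lapply(truth$shapes, unclass)),
      p("truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(vapply(c("subjects.csv", "activity.csv", "trials.csv",
                     "maps.csv", "covariates.csv", "rois.csv"),
                   p, character(1)))
}
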