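test_that("cohort generation respects range, determinism and motion shape", {
  coh <- generate_cohort(540, 6, 82, seed = 1)
  expect_equal(nrow(coh), 540)
  expect_true(all(coh$age >= 6 & coh$age <= 82))
  expect_false(anyDuplicated(coh$subject_id) > 0)
  expect_true(all(coh$mean_motion >= 0))
  expect_identical(coh, generate_cohort(540, 6, 82, seed = 1))

  # degenerate but valid range
  tiny <- generate_cohort(2, 10, 10.0001, seed = 1)
  expect_equal(tiny$age, c(10, 10), tolerance = 1e-3)

  # motion is U-shaped in age with the steeper limb in childhood
  a <- (coh$age - 6) / 76
  young <- mean(coh$mean_motion[a < 0.15])
  mid <- mean(coh$mean_motion[a > 0.3 & a < 0.5])
  old <- mean(coh$mean_motion[a > 0.85])
  expect_gt(young, mid)
  expect_gt(old, mid)
  expect_gt(young - mid, old - mid)

  expect_error(generate_cohort(1), "n must be")
  expect_error(generate_cohort(10, 50, 40), "age_min < age_max")
})

test_that("zero-noise activity equals the canonical curves exactly", {
  coh <- generate_cohort(60, seed = 2)
  tr <- ground_truth(n_rois = 12, cluster_sizes = c(2, 2, 2, 2, 2, 2),
                     noise_sd = 0)
  act <- generate_activity(coh, tr, seed = 3)
  a <- (coh$age - min(coh$age)) / diff(range(coh$age))
  for (roi in tr$roi_ids) {
    spec <- tr$shapes[[as.character(tr$assignment[roi])]]
    expect_equal(max(abs(act$activity[, roi] - eval_shape(spec, a))), 0)
  }
  # null ROIs are exactly zero
  null_rois <- names(tr$assignment)[tr$assignment == 0]
  expect_true(all(act$activity[, null_rois] == 0))
})

test_that("per-cluster mean activity curves track the generating shapes", {
  st <- planted_study()
  a <- (st$cohort$age - min(st$cohort$age)) / diff(range(st$cohort$age))
  for (cl in 1:5) {
    rois <- names(st$truth$assignment)[st$truth$assignment == cl]
    m <- rowMeans(st$activity[, rois])
    spec <- st$truth$shapes[[as.character(cl)]]
    # the mean curve (residual per-subject noise smoothed out by the age
    # fit; the raw per-subject correlation is noise-bounded below 0.95 for
    # the weak-amplitude shapes at the stated noise level)
    f <- fit_roi(m, st$cohort$age)
    ag <- (f$grid - min(st$cohort$age)) / diff(range(st$cohort$age))
    expect_gt(cor(f$fitted, eval_shape(spec, ag)), 0.95)
  }
})

test_that("trial generator hits chance and ceiling endpoints", {
  coh <- generate_cohort(40, seed = 4)
  # zero signal: Q3 at the 0.5 chance level, corrected index centered on 0
  tr0 <- generate_trials(coh, n_old = 2000, perf_curve = shape_spec("null"),
                         seed = 5, p_no_response = 0)
  sc0 <- score_subjects(tr0)
  expect_lt(abs(mean(sc0$corrected_index)), 0.02)
  # maximal signal: all trials source, index 1
  tr1 <- generate_trials(
    coh, n_old = 50,
    perf_curve = shape_spec("monotonic_up", amplitude = 0, baseline = 1),
    seed = 6, p_no_response = 0)
  sc1 <- score_subjects(tr1)
  expect_true(all(sc1$corrected_index == 1))
})

test_that("corrected source memory follows an inverted-U in age", {
  coh <- generate_cohort(300, seed = 7)
  trials <- generate_trials(coh, n_old = 100, seed = 8)
  sc <- score_subjects(trials)
  stopifnot(identical(sc$subject_id, coh$subject_id))
  f <- fit_roi(sc$corrected_index, coh$age)
  expect_gt(f$edf, 1)
  expect_lt(f$age_p, 1e-6)
  # inverted U: interior peak above both endpoint fits
  expect_gt(max(f$fitted[30:70]), f$fitted[1])
  expect_gt(max(f$fitted[30:70]), f$fitted[100])
})

test_that("brain maps carry the planted enrichment and expansion skew", {
  tr <- ground_truth()
  m0 <- generate_maps(tr, enriched_cluster = 4, effect = 0, seed = 9)
  m10 <- generate_maps(tr, enriched_cluster = 4, effect = 10, seed = 9)
  in4 <- tr$assignment == 4
  gap <- mean(m10$flexibility[in4]) - mean(m10$flexibility[!in4])
  expect_gt(gap, 8)
  expect_lt(abs(mean(m0$flexibility[in4]) - mean(m0$flexibility[!in4])), 1)
  # exponential-like marginal of expansion: positive skew on a large draw
  big <- ground_truth(n_rois = 2000, cluster_sizes = c(1995, 1, 1, 1, 1, 1))
  me <- generate_maps(big, enriched_cluster = 4, effect = 0, seed = 10)
  expect_gt(sample_skewness(me$expansion), 1)
  # surface-only maps are NA for subcortical ROIs
  coh <- generate_cohort(50, seed = 11)
  act <- generate_activity(coh, tr, seed = 11)
  mm <- generate_maps(tr, seed = 12, rois = act$rois)
  subcort <- !act$rois$cortical
  expect_true(any(subcort))
  expect_true(all(is.na(mm$gradient[subcort])))
  expect_true(all(!is.na(mm$flexibility)))
})

test_that("GM components hit their target age R-squared", {
  coh <- generate_cohort(540, seed = 13)
  cov <- generate_covariates(coh, seed = 14)
  r2 <- function(y) {
    m <- mgcv::gam(y ~ s(age, k = 10), data = data.frame(y = y, age = coh$age),
                   method = "REML")
    summary(m)$r.sq
  }
  expect_equal(r2(cov$gm_ic1), 0.86, tolerance = 0.05)
  expect_equal(r2(cov$gm_ic2), 0.46, tolerance = 0.08)
})

test_that("a coupled covariate is detected by the association stage", {
  st <- planted_study()
  cov <- generate_covariates(st$cohort, seed = 15,
                             coupling = list(score = "matrices", cluster = 4,
                                             partial_r = 0.4),
                             activity = st$activity, truth = st$truth)
  sc <- cluster_scores(st$activity, st$truth$assignment)
  sc4 <- sc[sc$cluster == 4, ]
  res <- gam_association(sc4$score, cov$matrices, st$cohort$age,
                         st$cohort$sex)
  expect_lt(res$p, 0.001)
})

test_that("simulate_study is deterministic and write_study round-trips", {
  s1 <- simulate_study(n = 40, n_rois = 12,
                       cluster_sizes = c(2, 2, 2, 2, 2, 2), seed = 3)
  s2 <- simulate_study(n = 40, n_rois = 12,
                       cluster_sizes = c(2, 2, 2, 2, 2, 2), seed = 3)
  expect_identical(s1$activity, s2$activity)
  expect_identical(s1$trials, s2$trials)
  dir <- withr::local_tempdir()
  paths <- write_study(s1, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(file.path(dir, "activity.csv"), check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), s1$activity, ignore_attr = TRUE)
})
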