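test_that("dissimilarity is the least-squares sum of derivative differences", {
  d <- rbind(a = c(0, 1, 2), b = c(1, 1, 1), c = c(0, 1, 2))
  D <- build_dissimilarity(d)
  expect_equal(D["a", "b"], 2)          # 1 + 0 + 1
  expect_equal(D["a", "c"], 0)          # identical vectors
  expect_equal(D["b", "b"], 0)
  expect_true(isSymmetric(D))
  # constant offset vector against zero: 100 * c^2
  d2 <- rbind(z = rep(0, 100), k = rep(0.3, 100))
  expect_equal(build_dissimilarity(d2)["z", "k"], 100 * 0.3^2)
  # effect flags subset the matrix
  flags <- data.frame(roi_id = c("a", "b", "c"),
                      has_effect = c(TRUE, FALSE, TRUE))
  expect_equal(rownames(build_dissimilarity(d, flags)), c("a", "c"))
})

test_that("PAM solves separable instances and canonicalizes labels", {
  # two tight pairs far apart
  x <- c(0, 0.1, 10, 10.1)
  D <- as.matrix(dist(x))^2
  rownames(D) <- colnames(D) <- paste0("p", 1:4)
  sol <- pam_fit(D, 2)
  expect_equal(unname(sol$assignment), c(1, 1, 2, 2))
  expect_equal(sol$objective, D["p1", "p2"] + D["p3", "p4"])
  expect_gt(sol$avg_silhouette, 0.9)
  # medoids belong to their own clusters
  expect_equal(unname(sol$assignment[sol$medoids]), 1:2)
  # k = n: every point its own medoid, objective 0
  soln <- pam_fit(D, 4)
  expect_equal(soln$objective, 0)
  expect_setequal(soln$medoids, rownames(D))
  # labels ordered by descending cluster size
  D5 <- as.matrix(dist(c(0, 0.1, 0.2, 9, 9.1, 20)))^2
  sol5 <- pam_fit(D5, 3)
  sizes <- as.integer(table(sol5$assignment))
  expect_true(all(diff(sizes) <= 0))
  expect_error(pam_fit(D, 1), "k must be")
  expect_error(pam_fit(D, 5), "cannot exceed")
})

test_that("PAM attains the brute-force optimum on random instances", {
  for (seed in 1:25) {
    D <- rand_diss(8, seed)
    for (k in 2:3) {
      expect_equal(pam_fit(D, k)$objective, brute_pam_objective(D, k),
                   tolerance = 1e-9)
    }
  }
})

test_that("silhouettes match hand computation on a fixed 4x4 matrix", {
  D <- matrix(c(0, 2, 6, 10,
                2, 0, 8, 4,
                6, 8, 0, 2,
                10, 4, 2, 0), 4, 4, byrow = TRUE)
  rownames(D) <- colnames(D) <- paste0("r", 1:4)
  s <- silhouette_widths(D, c(1, 1, 2, 2))
  # hand: s = (b - a)/max(a, b); a = within dist, b = mean to other pair
  expect_equal(s$sil_width, c((8 - 2) / 8, (6 - 2) / 6, (7 - 2) / 7,
                              (7 - 2) / 7), tolerance = 1e-12)
  # a == b gives s = 0
  De <- matrix(c(0, 2, 2, 2,
                 2, 0, 2, 2,
                 2, 2, 0, 2,
                 2, 2, 2, 0), 4, 4)
  se <- silhouette_widths(De, c(1, 1, 2, 2))
  expect_equal(se$sil_width, rep(0, 4))
  expect_true(all(abs(s$sil_width) <= 1))
  expect_error(silhouette_widths(D, c(1, 1, 1, 1)), "2 clusters")
})

test_that("silhouette selection finds the planted number of clusters", {
  # derivative vectors straight from two / five canonical shapes
  g <- seq(0, 1, length.out = 100)
  mk <- function(shape, m, amp) {
    base <- grid_derivative(amp * canonical_curve(shape, g), g)
    t(sapply(seq_len(m), function(i) base + rnorm(100, 0, 0.02)))
  }
  set.seed(40)
  d2 <- rbind(mk("monotonic_up", 6, 1), mk("u_shape", 6, 1))
  rownames(d2) <- sprintf("r%02d", 1:12)
  expect_equal(select_k(build_dissimilarity(d2), 2:6)$solution$k, 2)
  set.seed(41)
  d5 <- rbind(mk("monotonic_up", 6, 0.5), mk("u_shape", 6, 0.5),
              mk("weak_inverted_u", 6, 0.5), mk("steep_inverted_u", 6, 0.5),
              mk("developmental_plateau", 6, 0.4))
  rownames(d5) <- sprintf("r%02d", 1:30)
  sel <- select_k(build_dissimilarity(d5), 2:8)
  expect_equal(sel$solution$k, 5)
  expect_equal(nrow(sel$profile), 7)
})

test_that("adjusted Rand index behaves as a chance-corrected agreement", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 1)), 0)
  # known small case, hand-computed via the contingency formula:
  # a = (1,1,2,2,2), b = (1,2,1,2,2): sum_ij = 1, sum_a = sum_b = 4,
  # expected = 4*4/10 = 1.6 -> ARI = (1 - 1.6) / (4 - 1.6) = -0.25
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, 2), c(1, 2, 1, 2, 2)),
               -0.25, tolerance = 1e-12)
  set.seed(42)
  a <- sample(1:3, 200, TRUE)
  expect_lt(abs(adjusted_rand_index(a, sample(1:3, 200, TRUE))), 0.1)
})

test_that("clustering is invariant to a constant shift of one ROI column", {
  st <- simulate_study(n = 120, n_rois = 18,
                       cluster_sizes = c(3, 3, 3, 3, 3, 3), seed = 5)
  base <- run_pipeline(st$activity, st$cohort, k_range = 2:6)
  shifted <- st$activity
  roi <- names(base$solution$assignment)[1]
  shifted[, roi] <- shifted[, roi] + 10
  re <- run_pipeline(shifted, st$cohort, k_range = 2:6)
  expect_lt(max(abs(base$D - re$D)), 1e-8)
  expect_identical(base$solution$assignment, re$solution$assignment)
})

test_that("half-split with duplicated halves reproduces the solution", {
  st <- simulate_study(n = 100, n_rois = 18,
                       cluster_sizes = c(3, 3, 3, 3, 3, 3), seed = 6)
  # duplicating the cohort into both halves must give identical solutions
  act2 <- rbind(st$activity, st$activity)
  rownames(act2) <- sprintf("s%03d", seq_len(nrow(act2)))
  subj2 <- rbind(st$cohort, st$cohort)
  subj2$subject_id <- rownames(act2)
  hs <- half_split_replication(act2, subj2,
                               halves = list(1:100, 101:200), k_range = 2:6)
  expect_equal(hs$ari, 1)
  expect_identical(hs$half1$solution$assignment,
                   hs$half2$solution$assignment)
})

test_that("motion-sensitivity bookkeeping is exact", {
  st <- simulate_study(n = 140, n_rois = 18,
                       cluster_sizes = c(3, 3, 3, 3, 3, 3), seed = 8)
  full <- run_pipeline(st$activity, st$cohort, k_range = 2:6)
  ms0 <- motion_sensitivity(st$activity, st$cohort, fraction = 0,
                            full = full, k_range = 2:6)
  expect_equal(ms0$ari, 1)
  ms <- motion_sensitivity(st$activity, st$cohort, fraction = 0.10,
                           full = full, k_range = 2:6)
  expect_equal(length(ms$removed), ceiling(0.10 * 140))
  # removed subjects are exactly the top-motion ones
  thr <- sort(st$cohort$mean_motion, decreasing = TRUE)[14]
  expect_true(all(st$cohort$mean_motion[
    st$cohort$subject_id %in% ms$removed] >= thr))
  no_motion <- st$cohort[, setdiff(names(st$cohort), "mean_motion")]
  expect_error(motion_sensitivity(st$activity, no_motion), "mean_motion")
})
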