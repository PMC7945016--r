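# Shared fixtures and independent oracles. The planted full-scale study
# (120 ROIs x 300 subjects, noise_sd = 0.125, seed 1) and its pipeline run
# are computed once per session and reused.

.fixtures <- new.env(parent = emptyenv())

planted_study <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- simulate_study(n = 300, n_rois = 120,
                                      noise_sd = 0.125, seed = 1)
  .fixtures$study
}

planted_pipeline <- function() {
  if (is.null(.fixtures$pipe)) {
    st <- planted_study()
    .fixtures$pipe <- run_pipeline(st$activity, st$cohort, k_range = 2:10)
  }
  .fixtures$pipe
}

# small random squared-euclidean dissimilarity matrix
rand_diss <- function(n, seed, dim = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * dim), n)
  rownames(X) <- sprintf("r%02d", seq_len(n))
  as.matrix(dist(X))^2
}

# exhaustive k-medoids oracle: global optimum over all medoid subsets
brute_pam_objective <- function(D, k) {
  combs <- utils::combn(nrow(D), k)
  min(apply(combs, 2, function(med) {
    sum(apply(D[, med, drop = FALSE], 1, min))
  }))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# exact two-sided enrichment p-values by full label-permutation enumeration
enum_enrichment_p <- function(v, lab) {
  labs <- sort(unique(lab))
  P <- all_perms(length(v))
  sapply(labs, function(cl) {
    inc <- lab == cl
    obs <- mean(v[inc]) - mean(v[!inc])
    null_stat <- apply(P, 1, function(p) {
      vp <- v[p]
      mean(vp[inc]) - mean(vp[!inc])
    })
    mean(abs(null_stat) >= abs(obs) - 1e-12)
  })
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}
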