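test_that("block components are orthonormal and carry block structure", {
  # single community, no jitter: constant loadings up to sign/normalization
  comm1 <- factor(rep("A", 4))
  C1 <- make_block_components(comm1, K = 1, within_block_sd = 0, seed = 1)
  expect_equal(abs(as.numeric(C1)), rep(1 / sqrt(6), 6))

  # orthonormality contract across several configurations
  for (seed in 1:3) {
    comm <- even_communities(16, 4)
    C <- make_block_components(comm, K = 5, within_block_sd = 0.1, seed = seed)
    expect_equal(crossprod(C), diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  }

  expect_error(make_block_components(comm1, K = 7, within_block_sd = 0),
               "K > E")
  expect_error(make_block_components(comm1, K = 1, within_block_sd = -1),
               ">= 0")
})

test_that("block components are detected by the SBM permutation oracle", {
  comm <- even_communities(60, 4)
  C <- make_block_components(comm, K = 3, within_block_sd = 0.1, seed = 3)
  for (k in 1:3) {
    tst <- sbm_permutation_test(C[, k], comm, n_perm = 199, seed = 10 + k)
    expect_gt(tst$loglik_obs, quantile(tst$loglik_null, 0.95))
  }
})

test_that("nearest_psd_correlation repairs indefinite matrices and is a no-op on PSD input", {
  expect_equal(nearest_psd_correlation(diag(4)), diag(4))

  set.seed(5)
  A <- matrix(rnorm(40), 10, 4)
  R <- cov2cor(crossprod(A) + diag(4))
  expect_equal(nearest_psd_correlation(R), R, tolerance = 1e-10)

  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_lt(min(eigen(bad, symmetric = TRUE)$values), 0)
  fixed <- nearest_psd_correlation(bad)
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), 0)
  expect_equal(diag(fixed), rep(1, 3), tolerance = 1e-10)

  expect_error(nearest_psd_correlation(matrix(rnorm(9), 3, 3)), "symmetric")
})

test_that("simulate_subjects plants z = M exactly when no variation is requested", {
  cfg <- sim_config(n_subjects = 5,
                    community_assignment = even_communities(10, 2),
                    n_components = 0, eigen_spectrum = numeric(0),
                    mean_connectome_scale = 0.4, edge_noise_sd = 0,
                    with_time_series = FALSE, seed = 2)
  sim <- simulate_subjects(cfg)
  for (i in 2:5) expect_equal(sim$z_true[i, ], sim$z_true[1, ])
  expect_equal(as.numeric(sim$z_true[1, ]), sim$M)
})

test_that("long time series recover the repaired correlation matrix", {
  cfg <- sim_config(n_subjects = 3,
                    community_assignment = even_communities(8, 2),
                    n_components = 2, eigen_spectrum = c(1, 0.7),
                    edge_noise_sd = 0.05, timepoints_range = c(50000, 50000),
                    seed = 9)
  sim <- simulate_subjects(cfg)
  r_hat <- pearson_matrix(sim$time_series[[1]])
  expect_lt(max(abs(r_hat - sim$correlations[[1]])), 0.02)
})

test_that("score covariance recovers the planted spectrum (Monte-Carlo moments)", {
  cfg <- sim_config(n_subjects = 400,
                    community_assignment = even_communities(20, 4),
                    n_components = 10,
                    eigen_spectrum = seq(1.4, 0.5, length.out = 10),
                    edge_noise_sd = 0, with_time_series = FALSE, seed = 31)
  sim <- simulate_subjects(cfg)
  S <- var(sim$scores)
  planted <- cfg$eigen_spectrum^2
  expect_true(all(abs(diag(S) / planted - 1) < 0.15))
  off <- S[upper.tri(S)]
  expect_lt(max(abs(off)), 0.15 * max(planted))
})

test_that("simulation is deterministic given the seed and respects PSD/time contracts", {
  cfg <- small_sim$config
  sim2 <- simulate_subjects(cfg)
  expect_identical(small_sim$z_true, sim2$z_true)
  expect_identical(small_sim$time_series, sim2$time_series)
  expect_identical(small_sim$scores, sim2$scores)

  expect_true(all(small_sim$timepoints >= cfg$timepoints_range[1]))
  expect_true(all(small_sim$timepoints <= cfg$timepoints_range[2]))
  for (r in small_sim$correlations[1:5]) {
    expect_gte(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
    expect_equal(diag(r), rep(1, ncol(r)), tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("phenotypes follow the planted linear model in the scores", {
  b <- matrix(0, 4, 2)
  b[1, 1] <- 1          # phenotype 1 = score 1 exactly
  b[, 2] <- c(1, -1, 0.5, 0)
  phen <- simulate_phenotypes(small_sim, coefficients = b, noise_sd = 0, seed = 1)
  expect_equal(phen$phen1, small_sim$scores[, 1])
  expect_equal(phen$phen2, drop(small_sim$scores %*% b[, 2]))

  # signal fraction 1/2: corr(y, signal) ~ sqrt(0.5) at n = 400
  cfg <- sim_config(n_subjects = 400,
                    community_assignment = even_communities(20, 4),
                    n_components = 3, eigen_spectrum = c(1, 0.8, 0.6),
                    edge_noise_sd = 0, with_time_series = FALSE, seed = 17)
  sim <- simulate_subjects(cfg)
  bb <- matrix(c(1, 1, 1), 3, 1)
  signal <- drop(sim$scores %*% bb)
  noise_sd <- sd(signal)   # equal signal and noise variance (empirically scaled)
  phen <- simulate_phenotypes(sim, coefficients = bb, noise_sd = noise_sd, seed = 5)
  expect_equal(cor(phen$phen1, signal), sqrt(0.5), tolerance = 0.06 / sqrt(0.5))

  expect_error(simulate_phenotypes(small_sim, coefficients = matrix(1, 2, 1)),
               "n_components")
})

test_that("retest sessions share the latent connectome and behave at the limits", {
  rt <- simulate_retest(small_sim, seed = 8, mode = "z_noise",
                        session_noise_sd = 0.1)
  expect_equal(dim(rt$session1), dim(rt$session2))
  # identical sessions: every edge ICC is exactly 1
  rt_same <- rt
  rt_same$session2 <- rt_same$session1
  expect_equal(edge_icc(rt_same), rep(1, ncol(rt$session1)))

  # timeseries mode: session connectomes are noisy versions of the same truth
  rt_ts <- simulate_retest(small_sim, seed = 8)
  expect_equal(dim(rt_ts$session1), c(60L, n_edges(20)))
  # shared latent connectome shows through the finite-T sampling noise
  cors <- vapply(1:10, function(i) cor(rt_ts$session1[i, ], rt_ts$session2[i, ]), 0)
  expect_true(all(cors > 0.25))
  expect_gt(mean(cors), 0.5)

  # determinism
  rt2 <- simulate_retest(small_sim, seed = 8, mode = "z_noise",
                         session_noise_sd = 0.1)
  expect_identical(rt$session2, rt2$session2)
})
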