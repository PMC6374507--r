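# brute-force Gaussian log-likelihood oracle: block means + pooled variance,
# summing log-densities edge by edge
sbm_oracle_loglik <- function(w, community) {
  P <- length(community)
  ei <- edge_index(P)
  key <- paste(pmin(as.character(community)[ei$i + 1],
                    as.character(community)[ei$j + 1]),
               pmax(as.character(community)[ei$i + 1],
                    as.character(community)[ei$j + 1]))
  mu <- ave(w, key, FUN = mean)
  s2 <- max(mean((w - mu)^2), 1e-12)
  sum(dnorm(w, mu, sqrt(s2), log = TRUE))
}

test_that("sbm_profile_loglik matches the hand-computed 4-node example and the oracle", {
  z <- c("A", "A", "B", "B")
  m <- matrix(0, 4, 4)
  m[1, 2] <- 1.0                      # within-A
  m[3, 4] <- 2.0                      # within-B
  m[1, 3] <- 3.0; m[1, 4] <- 3.0; m[2, 3] <- 3.0; m[2, 4] <- 5.0  # A-B
  m <- m + t(m)
  fit <- sbm_profile_loglik(m, z)
  expect_equal(sort(unname(fit$block_means)), c(1.0, 2.0, 3.5))
  expect_equal(fit$sigma2, 0.5)
  expect_equal(fit$loglik, -3 * (log(2 * pi * 0.5) + 1))
  expect_equal(fit$loglik, sbm_oracle_loglik(vectorize_connectome(m), z))

  # single community: one Gaussian fitted to all edges
  fit1 <- sbm_profile_loglik(m, rep("A", 4))
  w <- vectorize_connectome(m)
  s2 <- mean((w - mean(w))^2)
  expect_equal(fit1$loglik, sum(dnorm(w, mean(w), sqrt(s2), log = TRUE)))

  # random graphs: fast implementation == oracle, both variance variants finite
  for (seed in 1:3) {
    g <- random_symmetric(7, seed)
    zz <- sample(c("x", "y", "z"), 7, replace = TRUE)
    expect_equal(sbm_profile_loglik(g, zz)$loglik,
                 sbm_oracle_loglik(vectorize_connectome(g), zz))
    expect_true(is.finite(sbm_profile_loglik(g, zz,
                                             variance = "per_block")$loglik))
  }
})

test_that("profile log-likelihood is invariant to community names and respects refinement", {
  g <- random_symmetric(10, 4)
  z1 <- rep(c("A", "B"), each = 5)
  z2 <- rep(c("blue", "red"), each = 5)   # same partition, new names
  expect_equal(sbm_profile_loglik(g, z1)$loglik,
               sbm_profile_loglik(g, z2)$loglik)
  # any partition fits at least as well as the single community (pooled
  # variance shrinks when block means absorb structure)
  for (seed in 5:8) {
    g <- random_symmetric(8, seed)
    z <- sample(c("a", "b", "c"), 8, replace = TRUE)
    expect_gte(sbm_profile_loglik(g, z)$loglik + 1e-10,
               sbm_profile_loglik(g, rep("a", 8))$loglik)
  }
})

test_that("perfect block structure floors the variance and maximizes the likelihood", {
  z <- rep(c("A", "B"), each = 3)
  block_vals <- c(AA = 1, AB = -1, BB = 2)
  ei <- edge_index(6)
  key <- paste0(substr(z[ei$i + 1], 1, 1), substr(z[ei$j + 1], 1, 1))
  key[key == "BA"] <- "AB"
  w <- unname(block_vals[key])
  fit <- sbm_profile_loglik(w, z)
  expect_true(fit$degenerate)
  expect_equal(fit$sigma2, 1e-12)
  # exhaustively check no same-size relabeling does better
  others <- combn(6, 3, function(idx) {
    zz <- rep("B", 6); zz[idx] <- "A"
    sbm_profile_loglik(w, zz)$loglik
  })
  expect_equal(max(others), fit$loglik)  # the true assignment is among them
  expect_true(sum(others >= fit$loglik - 1e-6) <= 2)  # only A/B swap ties
})

test_that("permutation test is deterministic, powerful on planted structure, and enumeration-consistent", {
  comm <- even_communities(20, 4)
  C1 <- make_block_components(comm, K = 1, within_block_sd = 0.05, seed = 2)
  t1 <- sbm_permutation_test(C1[, 1], comm, n_perm = 199, seed = 5)
  expect_equal(t1$p_value, 1 / 200)

  t2 <- sbm_permutation_test(C1[, 1], comm, n_perm = 199, seed = 5)
  expect_identical(t1$loglik_null, t2$loglik_null)

  # exact enumeration oracle on P = 6 (two communities of 3: 20 assignments)
  set.seed(6)
  g <- random_symmetric(6, 11)
  z <- rep(c("A", "B"), each = 3)
  obs <- sbm_profile_loglik(g, z)$loglik
  all_ll <- combn(6, 3, function(idx) {
    zz <- rep("B", 6); zz[idx] <- "A"
    sbm_profile_loglik(g, zz)$loglik
  })
  p_exact <- mean(all_ll >= obs - 1e-12)
  t3 <- sbm_permutation_test(g, z, n_perm = 1999, seed = 7)
  # permutation p converges to the enumeration p (Monte-Carlo error ~ 1/sqrt(n))
  expect_lt(abs(t3$p_value - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 1999) + 2 / 1999)

  expect_error(sbm_permutation_test(g, z, n_perm = 0), "n_perm")
})

test_that("null p-values are stochastically no smaller than uniform", {
  set.seed(8)
  z <- rep(c("A", "B"), each = 4)
  pvals <- replicate(100, {
    g <- matrix(0, 8, 8)
    g[lower.tri(g)] <- rnorm(28)
    g <- g + t(g)
    sbm_permutation_test(g, z, n_perm = 39,
                         seed = sample.int(1e6, 1))$p_value
  })
  # empirical CDF at each grid point must not exceed uniform + sampling slack
  for (q in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pvals <= q), q + 3 * sqrt(q * (1 - q) / 100))
  }
})

test_that("bonferroni_reject implements the FWER threshold", {
  m <- 809
  p <- rep(1, m)
  p[5] <- 6e-5   # just below 0.05 / 809 = 6.18e-5
  p[6] <- 7e-5   # just above
  dec <- bonferroni_reject(p, alpha = 0.05)
  expect_true(dec[5])
  expect_false(dec[6])
  expect_equal(sum(dec), 1L)
  expect_false(any(bonferroni_reject(rep(1, 10))))
  # oracle loop
  set.seed(9)
  pv <- runif(50)
  expect_equal(bonferroni_reject(pv, 0.1),
               vapply(pv, function(x) x < 0.1 / 50, TRUE))
  expect_error(bonferroni_reject(numeric(0)), "empty")
  expect_error(bonferroni_reject(c(0.5, 0)), "0, 1")
})

test_that("component structure profile flags planted components and calibrates on noise", {
  comm <- even_communities(20, 4)
  bas <- fit_pca(subset_subjects(true_z_dataset(rank6_sim), 1:80))
  prof <- component_structure_profile(bas, comm, n_perm = 199, seed = 12, k = 6)
  expect_true(all(prof$significant_bonferroni))
  expect_true(all(prof$p_value <= 0.05 / 6))

  # strongest structure: an exact block-pattern component dominates the profile
  Cb <- make_block_components(comm, K = 1, within_block_sd = 0, seed = 3)
  fake <- bas
  fake$components[, 2] <- Cb[, 1]
  prof2 <- component_structure_profile(fake, comm, n_perm = 99, seed = 13, k = 6)
  lift <- prof2$loglik_obs - prof2$null_median
  expect_equal(which.max(lift), 2L)

  # pure-noise loadings: observed loglik inside the null interval ~95% of the time
  set.seed(14)
  E <- n_edges(20)
  noise_bas <- bas
  noise_bas$components <- qr.Q(qr(matrix(rnorm(E * 30), E, 30)))
  noise_bas$K_max <- 30L
  prof3 <- component_structure_profile(noise_bas, comm, n_perm = 199,
                                       seed = 15, k = 30)
  inside <- mean(prof3$loglik_obs >= prof3$null_lo &
                 prof3$loglik_obs <= prof3$null_hi)
  expect_gte(inside, 0.8)
  expect_false(any(prof3$significant_bonferroni))
})
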