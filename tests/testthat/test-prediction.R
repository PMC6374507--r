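pred_ds <- true_z_dataset(rank6_sim)
pred_train <- subset_subjects(pred_ds, 1:80)
pred_test <- subset_subjects(pred_ds, 81:110)
pred_basis <- fit_pca(pred_train)

test_that("fit_bbs is exact OLS and predict_bbs applies it", {
  sc <- expression_scores(pred_basis, pred_train, k = 4)
  y <- 3 * sc$scores[, 1]
  m <- fit_bbs(sc, y)
  expect_equal(unname(m$B), c(3, 0, 0, 0), tolerance = 1e-8)
  expect_equal(m$intercept, 0, tolerance = 1e-8)

  m_const <- fit_bbs(sc, rep(2.5, 80))
  expect_equal(unname(m_const$B), rep(0, 4), tolerance = 1e-10)
  expect_equal(m_const$intercept, 2.5, tolerance = 1e-10)

  # normal-equations oracle on a random 50 x 5 instance
  set.seed(21)
  S <- matrix(rnorm(250), 50, 5)
  yy <- rnorm(50)
  fake <- structure(list(scores = S, subject_ids = as.character(1:50),
                         k = 5L, basis_id = "x"),
                    class = "expression_scores")
  m2 <- fit_bbs(fake, yy)
  D <- cbind(1, S)
  beta <- solve(crossprod(D), crossprod(D, yy))
  expect_equal(unname(c(m2$intercept, m2$B)), drop(beta), tolerance = 1e-8)

  # prediction on held-out scores: exact linear phenotype recovered exactly
  sc_te <- expression_scores(pred_basis, pred_test, k = 4)
  y_te_hat <- predict_bbs(m, sc_te)
  expect_equal(y_te_hat, 3 * sc_te$scores[, 1], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(predict_bbs(m2, fake), drop(D %*% beta), tolerance = 1e-10)

  wrong <- sc_te
  wrong$basis_id <- "other"
  expect_error(predict_bbs(m, wrong), "different basis")
  expect_error(fit_bbs(sc, c(y[-1], NA)), "missing")
})

test_that("cross-validated BBS recovers planted component signal without leakage", {
  # phenotype: noiseless linear combination of the first 3 planted components
  # (the tight planted spectrum lets PCA mix components within the top block,
  # so the guaranteed plateau starts once all 6 planted components are in)
  y <- drop(rank6_sim$scores[1:80, 1:3] %*% c(1, -1, 0.5))
  cv <- crossval_bbs(pred_train, y, k_grid = c(1, 3, 6), n_folds = 5, seed = 3)
  r <- cv$curve$mean_r
  expect_gt(r[cv$curve$k == 6], 0.95)
  expect_lt(r[cv$curve$k == 1], r[cv$curve$k == 6])

  # determinism
  cv2 <- crossval_bbs(pred_train, y, k_grid = c(1, 3, 6), n_folds = 5, seed = 3)
  expect_identical(cv$per_fold, cv2$per_fold)

  # no leakage: a fold's held-out predictions come from models that never saw
  # that fold's phenotypes, so perturbing fold-1 phenotypes leaves fold-1
  # predictions untouched
  set.seed(99)
  y_shuf <- y
  in_f1 <- cv$fold_id == 1
  y_shuf[in_f1] <- sample(y[in_f1])
  cv3 <- crossval_bbs(pred_train, y_shuf, k_grid = c(1, 3, 6), n_folds = 5,
                      seed = 3)
  expect_identical(cv$predictions[in_f1, ], cv3$predictions[in_f1, ])

  # null phenotype: CV correlation stays near zero
  set.seed(8)
  y_null <- rnorm(80)
  cv_null <- crossval_bbs(pred_train, y_null, k_grid = 3, n_folds = 5, seed = 4)
  expect_lt(abs(cv_null$curve$mean_r), 0.35)
})

test_that("CPM recovers planted edges, calibrates under the null, and handles tails", {
  # edge-level signal lives in the generator's unstructured mode: under
  # strong shared components single edges are not separately identifiable
  cfg <- sim_config(n_subjects = 400,
                    community_assignment = even_communities(30, 3),
                    n_components = 0, eigen_spectrum = numeric(0),
                    mean_connectome_scale = 0.3, edge_noise_sd = 0.2,
                    with_time_series = FALSE, seed = 311)
  ds <- true_z_dataset(simulate_subjects(cfg))
  cpm_test <- subset_subjects(ds, 301:400)
  set.seed(31)
  planted <- sample(ncol(ds$X), 20)
  S <- rowSums(ds$X[, planted])
  y <- S + rnorm(400, sd = 0.1 * sd(S))
  m <- fit_cpm(ds, y, p_threshold = 0.01)
  expect_gte(sum(m$edge_mask[planted]), 18)

  # prediction oracle: masked-edge sums through the fitted line
  pred <- predict_cpm(m, cpm_test)
  sums <- rowSums(cpm_test$X[, m$edge_mask, drop = FALSE])
  expect_equal(pred, m$intercept + m$slope * sums, tolerance = 1e-12)
  expect_gt(cor(pred, rowSums(cpm_test$X[, planted])), 0.7)

  # tail swap duality: negating the phenotype swaps positive/negative masks
  m_neg <- fit_cpm(ds, -y, p_threshold = 0.01, tail = "negative")
  expect_identical(m$edge_mask, m_neg$edge_mask)

  # degenerate path: no edge survives an impossibly strict threshold
  expect_warning(m_deg <- fit_cpm(ds, y, p_threshold = 1e-300,
                                  tail = "negative"), "degenerate")
  expect_true(m_deg$degenerate)
  expect_equal(predict_cpm(m_deg, cpm_test), rep(mean(y), 100))
})

test_that("CPM positive-tail mask size is binomially calibrated under a pure-noise phenotype", {
  set.seed(41)
  Ee <- n_edges(45)            # 990 edges, close to the nominal 1,000
  N <- 400
  ds <- assemble_dataset(matrix(rnorm(N * Ee), N, Ee))
  # positive tail selects with probability p_threshold / 2 per edge under
  # independence; total over replicates is binomial
  n_rep <- 50
  total <- 0
  for (b in seq_len(n_rep)) {
    y <- rnorm(N)
    m <- suppressWarnings(fit_cpm(ds, y, p_threshold = 0.01))
    total <- total + sum(m$edge_mask)
  }
  bound <- qbinom(c(0.005, 0.995), n_rep * Ee, 0.005)
  expect_gte(total, bound[1])
  expect_lte(total, bound[2])
})

test_that("residualization produces confound-orthogonal phenotypes", {
  set.seed(51)
  n <- 100
  Cf <- cbind(age = rnorm(n), fd = rnorm(n))
  y <- rnorm(n) + 0.5 * Cf[, 1]
  res <- residualize_phenotypes(y, Cf)
  expect_lt(max(abs(crossprod(cbind(1, Cf), res))), 1e-8)

  # phenotype equal to a confound: residual identically zero
  expect_equal(residualize_phenotypes(Cf[, 1], Cf), rep(0, n),
               tolerance = 1e-10, ignore_attr = TRUE)

  # orthogonal confound: phenotype unchanged up to mean removal
  y2 <- rnorm(n)
  Cf2 <- cbind(conf = residualize_phenotypes(rnorm(n), cbind(y2)))
  res2 <- residualize_phenotypes(y2, Cf2)
  expect_equal(res2, y2 - mean(y2) , tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(residualize_phenotypes(y, cbind(Cf, Cf[, 1])), "collinear")
})

test_that("dependent-correlation comparison behaves at its reference points", {
  set.seed(61)
  actual <- rnorm(100)
  noise_pred <- rnorm(100)
  good_pred <- actual + rnorm(100, sd = 0.1)

  same <- compare_methods(actual, good_pred, good_pred)
  expect_equal(same$diff, 0)
  expect_equal(same$p_value, 1)

  cmp <- compare_methods(actual, good_pred, noise_pred)
  expect_lt(cmp$p_value, 0.05)
  expect_gt(cmp$r_a, cmp$r_b)

  # invariance to affine rescaling of predictions
  cmp2 <- compare_methods(actual, 10 * good_pred - 3, 2 * noise_pred + 1)
  expect_equal(cmp2$r_a, cmp$r_a, tolerance = 1e-12)
  expect_equal(cmp2$z, cmp$z, tolerance = 1e-12)

  expect_warning(bad <- compare_methods(actual, rep(1, 100), noise_pred),
                 "constant")
  expect_true(is.na(bad$p_value))
})
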