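# Shared synthetic fixtures, built once per test run.  Sizes are kept small:
# the full study-scale scenarios live in test-acceptance.R.

# small cohort with planted structure and time series
small_sim <- local({
  cfg <- sim_config(
    n_subjects = 60,
    community_assignment = even_communities(20, 4),
    n_components = 4,
    eigen_spectrum = c(1, 0.8, 0.6, 0.5),
    mean_connectome_scale = 0.3,
    edge_noise_sd = 0.03,
    timepoints_range = c(80, 100),
    seed = 42)
  simulate_subjects(cfg)
})

# z-only cohort, exact planted rank 6 (no edge noise); first 80 subjects act
# as the training sample, the rest as held-out data from the same truth
rank6_sim <- local({
  cfg <- sim_config(
    n_subjects = 110,
    community_assignment = even_communities(20, 4),
    n_components = 6,
    eigen_spectrum = c(1.2, 1, 0.9, 0.8, 0.7, 0.6),
    mean_connectome_scale = 0.3,
    edge_noise_sd = 0,
    with_time_series = FALSE,
    seed = 7)
  simulate_subjects(cfg)
})

random_symmetric <- function(P, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(P * P), P, P)
  m <- m + t(m)
  diag(m) <- 0
  m
}

# independent ICC(2,1) oracle via a two-way ANOVA fitted with aov()
icc_aov_oracle <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subj = factor(rep(seq_len(n), k)),
                   sess = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(y ~ subj + sess, data = df))[[1]][["Mean Sq"]]
  bms <- ms[1]; jms <- ms[2]; ems <- ms[3]
  (bms - ems) / (bms + (k - 1) * ems + k * (jms - ems) / n)
}
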