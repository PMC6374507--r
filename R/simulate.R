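#' Simulation configuration for synthetic connectome cohorts
#'
#' Defines the full generative recipe: a population-mean Fisher-z connectome
#' with intrinsic-connectivity-network (ICN) block structure, K planted
#' orthonormal block-structured components of inter-individual variation
#' weighted by subject scores with a prescribed spectrum, unstructured edge
#' noise, per-subject multivariate-normal ROI time series of variable length,
#' phenotypes linearly coupled to component scores, and optional paired
#' retest sessions sharing each subject's latent connectome.
#'
#' @param n_subjects number of subjects N.
#' @param community_assignment integer/character vector of length P mapping
#'   each node to a community (every community must have at least 2 nodes).
#' @param n_components number of planted components K (K < N).
#' @param eigen_spectrum length-K vector of per-component score standard
#'   deviations, strictly positive and non-increasing.
#' @param mean_connectome_scale magnitude of the shared block-structured
#'   population-mean z-values (0 disables the shared backbone).
#' @param edge_noise_sd standard deviation of subject-specific unstructured
#'   z-noise per edge (>= 0).
#' @param within_block_sd edge-level jitter inside each component's blocks,
#'   relative to the unit-scale block base values.
#' @param timepoints_range integer c(T_min, T_max); per-subject series length
#'   is uniform on this range (T_min >= 3).
#' @param n_phenotypes number of phenotype columns.
#' @param phenotype_coefficients K x n_phenotypes coefficient matrix linking
#'   component scores to phenotypes.
#' @param phenotype_noise_sd phenotype noise standard deviation (>= 0).
#' @param retest generate a second session per subject.
#' @param with_time_series draw ROI time series (set FALSE to work with the
#'   planted z-connectomes directly, which is much faster for large P).
#' @param seed integer master seed; all randomness derives from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects,
                       community_assignment,
                       n_components,
                       eigen_spectrum,
                       mean_connectome_scale = 0.3,
                       edge_noise_sd = 0.05,
                       within_block_sd = 0.1,
                       timepoints_range = c(150L, 200L),
                       n_phenotypes = 0L,
                       phenotype_coefficients = NULL,
                       phenotype_noise_sd = 0,
                       retest = FALSE,
                       with_time_series = TRUE,
                       seed = 1L) {
  community_assignment <- as.factor(community_assignment)
  P <- length(community_assignment)
  if (P < 3) stop("need at least 3 nodes")
  if (any(table(community_assignment) < 2)) stop("every community needs >= 2 nodes")
  if (n_components < 0 || n_components >= n_subjects)
    stop("need 0 <= n_components < n_subjects")
  if (length(eigen_spectrum) != n_components)
    stop("eigen_spectrum must have length n_components")
  if (any(eigen_spectrum <= 0)) stop("eigen_spectrum must be strictly positive")
  if (any(diff(eigen_spectrum) > 0)) stop("eigen_spectrum must be non-increasing")
  if (edge_noise_sd < 0) stop("edge_noise_sd must be >= 0")
  if (within_block_sd < 0) stop("within_block_sd must be >= 0")
  timepoints_range <- as.integer(round(timepoints_range))
  if (length(timepoints_range) != 2 || timepoints_range[1] > timepoints_range[2] ||
      timepoints_range[1] < 3)
    stop("timepoints_range must be c(T_min, T_max) with 3 <= T_min <= T_max")
  if (n_phenotypes > 0) {
    if (is.null(phenotype_coefficients))
      stop("phenotype_coefficients required when n_phenotypes > 0")
    phenotype_coefficients <- as.matrix(phenotype_coefficients)
    if (!all(dim(phenotype_coefficients) == c(n_components, n_phenotypes)))
      stop("phenotype_coefficients must be n_components x n_phenotypes")
  }
  if (phenotype_noise_sd < 0) stop("phenotype_noise_sd must be >= 0")
  structure(
    list(n_subjects = as.integer(n_subjects),
         community_assignment = community_assignment,
         P = P,
         n_components = as.integer(n_components),
         eigen_spectrum = as.numeric(eigen_spectrum),
         mean_connectome_scale = mean_connectome_scale,
         edge_noise_sd = edge_noise_sd,
         within_block_sd = within_block_sd,
         timepoints_range = timepoints_range,
         n_phenotypes = as.integer(n_phenotypes),
         phenotype_coefficients = phenotype_coefficients,
         phenotype_noise_sd = phenotype_noise_sd,
         retest = isTRUE(retest),
         with_time_series = isTRUE(with_time_series),
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Evenly sized community assignment
#' @param P number of nodes.
#' @param C number of communities.
#' @return factor of length P with C near-equal communities.
#' @export
even_communities <- function(P, C) {
  factor(rep_len(paste0("ICN", seq_len(C)), P)[order(rep_len(seq_len(C), P))],
         levels = paste0("ICN", seq_len(C)))
}

# block id per edge for a community assignment: unordered community pair key
block_of_edges <- function(community_assignment) {
  z <- as.integer(as.factor(community_assignment))
  P <- length(z)
  ei <- edge_index(P)
  a <- z[ei$i + 1L]
  b <- z[ei$j + 1L]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  lo + hi * (hi - 1L) / 2L   # triangular pair key, unique per unordered pair
}

# one raw block-patterned edge vector: a base value per community-pair block,
# constant across that block, plus optional edge-level jitter
raw_block_vector <- function(block, within_block_sd) {
  lev <- sort(unique(block))
  base <- stats::rnorm(length(lev))
  v <- base[match(block, lev)]
  if (within_block_sd > 0) v <- v + stats::rnorm(length(v), sd = within_block_sd)
  v
}

#' Generate orthonormal block-structured latent components
#'
#' Each component is built by drawing one base value per unordered community
#' pair, assigning it to every edge in that block, adding edge-level jitter
#' of scale `within_block_sd`, and then orthonormalizing the vectorized set
#' by sequential Gram-Schmidt projection and normalization.  The result is a
#' set of unit-norm, mutually orthogonal edge-space loadings that carry the
#' ICN block structure the downstream stochastic-block-model test detects.
#'
#' @param community_assignment node-to-community labels (length P).
#' @param K number of components.
#' @param within_block_sd edge-level jitter scale (>= 0).
#' @param seed integer seed.
#' @return E x K loading matrix with attribute `community_assignment`;
#'   columns have unit Euclidean norm and pairwise |dot| < 1e-8.
#' @export
make_block_components <- function(community_assignment, K, within_block_sd = 0.1,
                                  seed = 1L) {
  community_assignment <- as.factor(community_assignment)
  if (K < 1) stop("K must be >= 1")
  if (within_block_sd < 0) stop("within_block_sd must be >= 0")
  P <- length(community_assignment)
  E <- n_edges(P)
  if (K > E) stop("cannot orthonormalize more components than edges (K > E)")
  set.seed(seed)
  block <- block_of_edges(community_assignment)
  C <- matrix(NA_real_, E, K)
  k <- 0L
  tries <- 0L
  while (k < K) {
    v <- raw_block_vector(block, within_block_sd)
    if (k > 0) {
      Q <- C[, seq_len(k), drop = FALSE]
      v <- v - Q %*% crossprod(Q, v)
    }
    nv <- sqrt(sum(v^2))
    tries <- tries + 1L
    if (nv < 1e-10 * sqrt(E)) {
      if (tries > 50L * K) stop("failed to generate ", K, " independent block components")
      next  # degenerate draw (collinear with previous), redraw
    }
    k <- k + 1L
    C[, k] <- v / nv
  }
  attr(C, "community_assignment") <- community_assignment
  C
}

#' Repair a correlation matrix to the positive semidefinite cone
#'
#' Eigenvalues below `eig_floor` are clipped up to `eig_floor`, the matrix is
#' reconstructed, and the diagonal is rescaled back to 1 (congruence by
#' D^{-1/2} on both sides, which preserves positive semidefiniteness).
#'
#' @param R symmetric matrix with unit diagonal (tolerance 1e-8).
#' @param eig_floor minimum retained eigenvalue (default 1e-6).
#' @return symmetric correlation matrix with unit diagonal and smallest
#'   eigenvalue >= 0; returned unchanged (up to 1e-10) when already
#'   sufficiently positive definite.
#' @export
nearest_psd_correlation <- function(R, eig_floor = 1e-6) {
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-8) stop("input must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("input must have unit diagonal")
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eig_floor) return(R)
  lam <- pmax(e$values, eig_floor)
  R2 <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  0.5 * (R2 + t(R2))
}

#' Simulate a cohort of subjects with planted low-rank connectome structure
#'
#' For each subject i, scores s_ik ~ N(0, eigen_spectrum[k]^2); the planted
#' Fisher-z connectome is z_i = M + sum_k s_ik C_k + eps_i with eps_i i.i.d.
#' N(0, edge_noise_sd^2) per edge and M a fixed block-structured mean scaled
#' by `mean_connectome_scale`.  Correlations are r_i = tanh(z_i) with unit
#' diagonal, repaired to a valid correlation matrix by
#' [nearest_psd_correlation()]; when `with_time_series` is set, T_i i.i.d.
#' multivariate-normal rows with covariance r_i are drawn, T_i uniform on
#' `timepoints_range`.  Fully deterministic given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return object of class `sim_data`: list with `config`, `components`
#'   (E x K), `M` (E-vector), `scores` (N x K), `z_true` (N x E planted
#'   z-connectomes), `correlations` (list of repaired P x P matrices),
#'   `time_series` (list of T_i x P matrices or NULL), `timepoints`,
#'   `subject_ids`, `node_ids`.
#' @export
simulate_subjects <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  P <- cfg$P
  E <- n_edges(P)
  N <- cfg$n_subjects
  K <- cfg$n_components
  components <- if (K > 0)
    make_block_components(cfg$community_assignment, K,
                          cfg$within_block_sd, seed = cfg$seed)
  else matrix(numeric(0), E, 0)
  set.seed(cfg$seed + 1L)
  block <- block_of_edges(cfg$community_assignment)
  M <- cfg$mean_connectome_scale * raw_block_vector(block, cfg$within_block_sd)
  scores <- matrix(stats::rnorm(N * K), N, K)
  if (K > 0) scores <- scores %*% diag(cfg$eigen_spectrum, K)
  Z <- scores %*% t(components)
  Z <- sweep(Z, 2, M, "+")
  if (cfg$edge_noise_sd > 0)
    Z <- Z + matrix(stats::rnorm(N * E, sd = cfg$edge_noise_sd), N, E)
  node_ids <- sprintf("node%03d", seq_len(P))
  subject_ids <- sprintf("sub%04d", seq_len(N))
  tp_seq <- seq.int(cfg$timepoints_range[1], cfg$timepoints_range[2])
  timepoints <- tp_seq[sample.int(length(tp_seq), N, replace = TRUE)]
  # correlation matrices (and their PSD repair) are only materialized when
  # time series are requested; z-only runs stay cheap at large P
  correlations <- if (cfg$with_time_series) vector("list", N) else NULL
  time_series <- if (cfg$with_time_series) vector("list", N) else NULL
  if (cfg$with_time_series) {
    for (i in seq_len(N)) {
      r <- devectorize_connectome(tanh(Z[i, ]), P)
      diag(r) <- 1
      r <- nearest_psd_correlation(r)
      if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
        stop("PSD repair failed for subject ", i)
      dimnames(r) <- list(node_ids, node_ids)
      correlations[[i]] <- r
      ts <- MASS::mvrnorm(timepoints[i], mu = rep(0, P), Sigma = r)
      colnames(ts) <- node_ids
      time_series[[i]] <- ts
    }
  }
  structure(
    list(config = cfg, components = components, M = M, scores = scores,
         z_true = Z, correlations = correlations, time_series = time_series,
         timepoints = timepoints, subject_ids = subject_ids,
         node_ids = node_ids),
    class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat("sim_data:", x$config$n_subjects, "subjects, P =", x$config$P,
      "nodes, K =", x$config$n_components, "planted components",
      if (x$config$with_time_series) "(with time series)" else "(z only)", "\n")
  invisible(x)
}

#' Planted z-connectomes as a connectome dataset
#'
#' Assembles the generator's noiseless-measurement latent z-connectomes
#' (planted mean + components + edge noise, before any time-series sampling)
#' into a [assemble_dataset()] container.
#'
#' @param sim a `sim_data` object.
#' @return a `connectome_dataset`.
#' @export
true_z_dataset <- function(sim) {
  stopifnot(inherits(sim, "sim_data"))
  assemble_dataset(sim$z_true, sim$subject_ids, sim$node_ids)
}

#' Observed connectome dataset from simulated time series
#'
#' Runs each subject's simulated series through [z_connectome()] and
#' assembles the subjects x edges matrix.
#'
#' @param sim a `sim_data` object generated with `with_time_series = TRUE`.
#' @param clip passed to [fisher_z()].
#' @return a `connectome_dataset`.
#' @export
observed_dataset <- function(sim, clip = FALSE) {
  stopifnot(inherits(sim, "sim_data"))
  if (is.null(sim$time_series)) stop("simulation was run without time series")
  zs <- lapply(sim$time_series, z_connectome, clip = clip)
  assemble_dataset(zs, sim$subject_ids, sim$node_ids)
}

#' Simulate phenotypes linearly coupled to component scores
#'
#' y_ij = sum_k s_ik b_kj + N(0, phenotype_noise_sd^2).
#'
#' @param sim a `sim_data` object.
#' @param coefficients K x n_phenotypes matrix (defaults to the config's).
#' @param noise_sd phenotype noise sd (defaults to the config's).
#' @param seed integer seed.
#' @return data.frame: `subject_id` plus one numeric column per phenotype.
#' @export
simulate_phenotypes <- function(sim, coefficients = NULL, noise_sd = NULL,
                                seed = NULL) {
  stopifnot(inherits(sim, "sim_data"))
  cfg <- sim$config
  if (is.null(coefficients)) coefficients <- cfg$phenotype_coefficients
  if (is.null(coefficients)) stop("no phenotype coefficients available")
  coefficients <- as.matrix(coefficients)
  if (nrow(coefficients) != cfg$n_components)
    stop("coefficients must have n_components rows")
  if (is.null(noise_sd)) noise_sd <- cfg$phenotype_noise_sd
  if (is.null(seed)) seed <- cfg$seed + 2L
  set.seed(seed)
  Y <- sim$scores %*% coefficients
  if (noise_sd > 0)
    Y <- Y + matrix(stats::rnorm(length(Y), sd = noise_sd), nrow(Y), ncol(Y))
  out <- data.frame(subject_id = sim$subject_ids, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(Y))) out[[paste0("phen", j)]] <- Y[, j]
  out
}

#' Simulate confound variables
#'
#' Confounds are independent of the planted component scores by default; a
#' coupling matrix mixes scores in for testing residualization behaviour.
#'
#' @param sim a `sim_data` object.
#' @param n_confounds number of confound columns.
#' @param coupling optional K x n_confounds matrix of score loadings.
#' @param seed integer seed.
#' @return data.frame: `subject_id` plus one column per confound.
#' @export
simulate_confounds <- function(sim, n_confounds = 2L, coupling = NULL,
                               seed = NULL) {
  stopifnot(inherits(sim, "sim_data"))
  if (is.null(seed)) seed <- sim$config$seed + 3L
  set.seed(seed)
  N <- sim$config$n_subjects
  Cf <- matrix(stats::rnorm(N * n_confounds), N, n_confounds)
  if (!is.null(coupling)) Cf <- Cf + sim$scores %*% as.matrix(coupling)
  out <- data.frame(subject_id = sim$subject_ids, stringsAsFactors = FALSE)
  for (j in seq_len(n_confounds)) out[[paste0("conf", j)]] <- Cf[, j]
  out
}

#' Simulate a paired retest session
#'
#' Two modes.  `"timeseries"` (default): session 2 time series are drawn
#' independently from each subject's latent correlation matrix, so both
#' sessions share the subject's true connectome and differ only by sampling
#' noise; session-1 connectomes come from the original simulated series.
#' `"z_noise"`: both sessions are the subject's planted z-connectome plus
#' independent i.i.d. N(0, session_noise_sd^2) edge noise, which plants a
#' known within-subject variance directly in z-space (useful for calibrating
#' reliability statistics against a chosen between/within variance ratio).
#'
#' @param sim a `sim_data` object.
#' @param seed integer seed.
#' @param mode `"timeseries"` or `"z_noise"`.
#' @param session_noise_sd per-edge within-subject z noise sd (z_noise mode).
#' @param clip passed to [fisher_z()] (timeseries mode).
#' @return object of class `retest_dataset`: `session1` and `session2`
#'   (N x E matrices), `subject_ids`, `P`.
#' @export
simulate_retest <- function(sim, seed = NULL,
                            mode = c("timeseries", "z_noise"),
                            session_noise_sd = 0.1, clip = FALSE) {
  stopifnot(inherits(sim, "sim_data"))
  mode <- match.arg(mode)
  if (is.null(seed)) seed <- sim$config$seed + 4L
  set.seed(seed)
  N <- sim$config$n_subjects
  P <- sim$config$P
  E <- n_edges(P)
  if (mode == "timeseries") {
    if (is.null(sim$time_series)) stop("simulation was run without time series")
    s1 <- t(vapply(sim$time_series,
                   function(ts) vectorize_connectome(z_connectome(ts, clip = clip)),
                   numeric(E)))
    s2 <- matrix(NA_real_, N, E)
    for (i in seq_len(N)) {
      ts2 <- MASS::mvrnorm(sim$timepoints[i], mu = rep(0, P),
                           Sigma = sim$correlations[[i]])
      s2[i, ] <- vectorize_connectome(z_connectome(ts2, clip = clip))
    }
  } else {
    noise <- function() matrix(stats::rnorm(N * E, sd = session_noise_sd), N, E)
    s1 <- sim$z_true + noise()
    s2 <- sim$z_true + noise()
  }
  rownames(s1) <- rownames(s2) <- sim$subject_ids
  structure(list(session1 = s1, session2 = s2,
                 subject_ids = sim$subject_ids, P = P),
            class = "retest_dataset")
}

#' @export
print.retest_dataset <- function(x, ...) {
  cat("retest_dataset:", length(x$subject_ids), "subjects x",
      ncol(x$session1), "edges, 2 sessions\n")
  invisible(x)
}
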