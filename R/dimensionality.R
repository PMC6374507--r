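#' Levina-Bickel maximum-likelihood intrinsic dimensionality estimate
#'
#' Estimates the intrinsic dimensionality of a point cloud from ratios of
#' nearest-neighbour Euclidean distances.  For each point x and neighbour
#' count k, the local estimate is
#' \deqn{\hat m_k(x) = \left[\frac{1}{k-2}\sum_{j=1}^{k-1}
#'   \log\frac{T_k(x)}{T_j(x)}\right]^{-1}}
#' where T_j(x) is the distance from x to its j-th nearest neighbour
#' (excluding x itself).  Estimates are averaged over points for each k and
#' then over k from `k1` to `k2` (defaults 10 and 20, the range recommended
#' by the method's authors).  The 1/(k-2) normalization is the
#' asymptotically unbiased variant; `normalization = "mle"` switches to the
#' raw maximum-likelihood 1/(k-1).
#'
#' @param X numeric N x D data matrix (rows are points).
#' @param k1,k2 neighbour range, 3 <= k1 <= k2 < N.
#' @param normalization `"unbiased"` (1/(k-2), default) or `"mle"` (1/(k-1)).
#' @param jitter if TRUE, exactly duplicated points are perturbed by
#'   N(0, (1e-9 sd(X))^2) noise instead of raising an error.
#' @return object of class `dimensionality_estimate`: `m_hat` (final
#'   estimate), `per_k` (mean estimate per k), `per_point` (N x n_k matrix),
#'   `k1`, `k2`, `normalization`.
#' @export
levina_bickel <- function(X, k1 = 10L, k2 = 20L,
                          normalization = c("unbiased", "mle"),
                          jitter = FALSE) {
  normalization <- match.arg(normalization)
  X <- as.matrix(X)
  N <- nrow(X)
  if (k1 < 3) stop("k1 must be >= 3 (the k-2 normalization degenerates)")
  if (k2 < k1) stop("k2 must be >= k1")
  if (N <= k2 + 1) stop("need more than k2 + 1 points")
  if (anyDuplicated(X)) {
    if (!jitter) stop("duplicate points give zero neighbour distances; ",
                      "enable jitter or de-duplicate")
    X <- X + matrix(stats::rnorm(length(X), sd = 1e-9 * stats::sd(X)),
                    nrow(X), ncol(X))
  }
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  ks <- k1:k2
  per_point <- matrix(NA_real_, N, length(ks))
  for (n in seq_len(N)) {
    d <- sort.int(D[n, ], partial = seq_len(k2))[seq_len(k2)]
    if (d[1] <= 0) stop("zero nearest-neighbour distance at point ", n)
    logd <- log(d)
    cs <- cumsum(logd)
    for (a in seq_along(ks)) {
      k <- ks[a]
      denom <- if (normalization == "unbiased") k - 2 else k - 1
      s <- (k - 1) * logd[k] - cs[k - 1]   # sum_j log(T_k / T_j), j = 1..k-1
      per_point[n, a] <- denom / s
    }
  }
  per_k <- colMeans(per_point)
  structure(
    list(m_hat = mean(per_k), per_k = per_k, per_point = per_point,
         k1 = as.integer(k1), k2 = as.integer(k2),
         normalization = normalization),
    class = "dimensionality_estimate")
}

#' @export
print.dimensionality_estimate <- function(x, ...) {
  cat(sprintf("Levina-Bickel intrinsic dimensionality: %.2f (k = %d..%d, %s)\n",
              x$m_hat, x$k1, x$k2, x$normalization))
  invisible(x)
}

#' Percent variance explained from eigenvalues
#'
#' @param eigenvalues non-negative eigenvalues (small negatives below
#'   -1e-10 are an error; larger ones are clipped to 0).
#' @return percentages 100 * lambda / sum(lambda), order preserved,
#'   summing to 100.
#' @export
percent_variance <- function(eigenvalues) {
  if (any(eigenvalues < -1e-10)) stop("negative eigenvalue")
  ev <- pmax(eigenvalues, 0)
  s <- sum(ev)
  if (s == 0) stop("all eigenvalues are zero")
  100 * ev / s
}

# reduce every subject's series to the common minimum length by random row
# retention, preserving temporal order (consumes the current RNG stream)
truncate_common <- function(timeseries_list) {
  T_common <- min(vapply(timeseries_list, nrow, 0L))
  lapply(timeseries_list, function(ts) {
    if (nrow(ts) > T_common)
      ts[sort(sample.int(nrow(ts), T_common)), , drop = FALSE]
    else ts
  })
}

# one ROI-swap draw: each node column independently gets a uniformly random
# permutation of subjects (each subject's node-j series used exactly once)
shuffle_node_columns <- function(arr) {
  N <- dim(arr)[3]
  out <- arr
  for (j in seq_len(dim(arr)[2])) {
    out[, j, ] <- arr[, j, sample.int(N)]
  }
  out
}

#' ROI-swap permutation null for the percent-variance spectrum
#'
#' Calibrates the observed PCA percent-variance-explained spectrum of a
#' subjects x edges connectome dataset against the null hypothesis of no
#' dependence between ROIs within a subject.  Subjects' series are first
#' reduced to the common minimum length T_common by seeded random row
#' retention (temporal order preserved).  For each permutation, every node
#' column independently receives a uniformly random permutation of subjects
#' (each subject's node-j series is used exactly once), which destroys
#' within-subject inter-node dependence while preserving each node's pooled
#' across-subject distribution; connectomes are then rebuilt, PCA run, and
#' the percent-variance spectrum recorded.  The observed spectrum is
#' computed on the unshuffled truncated data the same way.
#'
#' @param timeseries_list list of T_i x P matrices, one per subject, sharing
#'   the node set.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param clip passed to [fisher_z()].
#' @return object of class `null_spectrum`: `observed_percents`,
#'   `null_percents` (n_perm x n_components), `n_perm`, `seed`, `T_common`.
#' @export
roi_swap_null <- function(timeseries_list, n_perm = 50L, seed = 1L,
                          clip = FALSE) {
  if (length(timeseries_list) < 2) stop("need at least 2 subjects")
  if (n_perm < 1) stop("n_perm must be >= 1")
  P <- ncol(timeseries_list[[1]])
  if (!all(vapply(timeseries_list, ncol, 0L) == P))
    stop("all subjects must share the node set")
  N <- length(timeseries_list)
  set.seed(seed)
  trunc_list <- truncate_common(timeseries_list)
  T_common <- nrow(trunc_list[[1]])
  # stack into T_common x P x N array for fast column swapping
  arr <- array(unlist(trunc_list, use.names = FALSE), dim = c(T_common, P, N))
  spectrum_of <- function(a) {
    zs <- lapply(seq_len(N), function(i) z_connectome(a[, , i], clip = clip))
    ds <- assemble_dataset(zs)
    percent_variance(fit_pca(ds)$eigenvalues)
  }
  observed <- spectrum_of(arr)
  null_percents <- matrix(NA_real_, n_perm, length(observed))
  for (b in seq_len(n_perm)) {
    null_percents[b, ] <- spectrum_of(shuffle_node_columns(arr))
  }
  structure(
    list(observed_percents = observed, null_percents = null_percents,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         T_common = as.integer(T_common)),
    class = "null_spectrum")
}

#' @export
print.null_spectrum <- function(x, ...) {
  cat("null_spectrum:", x$n_perm, "ROI-swap permutations, T_common =",
      x$T_common, "\n")
  cat(sprintf("  observed top percent %.2f vs null top max %.2f\n",
              x$observed_percents[1], max(x$null_percents[, 1])))
  invisible(x)
}
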