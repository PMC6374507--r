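#' Gaussian SBM profile log-likelihood of a weighted graph
#'
#' Fits a weighted stochastic block model with FIXED node-community
#' assignments: each unordered community pair (a, b) gets its own Gaussian
#' mean mu_ab estimated as the mean edge weight inside that block, with a
#' single pooled residual variance across all E edges (profiled out at its
#' MLE; a per-block variance variant is available behind `variance`).
#' The profile log-likelihood at the MLE is
#' \deqn{\ell = -\frac{E}{2}\left(\log(2\pi\hat\sigma^2) + 1\right)}
#' (pooled case); larger values indicate stronger block structure.  The
#' variance is floored at 1e-12 so degenerate inputs yield a finite,
#' flagged value instead of -Inf.
#'
#' @param graph symmetric P x P weight matrix (diagonal ignored) or an
#'   E-vector of edge weights in canonical [edge_index()] order.
#' @param community node-to-community assignment of length P.
#' @param variance `"pooled"` (default) or `"per_block"`.
#' @return object of class `sbm_fit`: `block_means` (named by community
#'   pair), `sigma2` (pooled) or `block_sigma2`, `loglik`, `n_edges`,
#'   `degenerate`.
#' @export
sbm_profile_loglik <- function(graph, community,
                               variance = c("pooled", "per_block")) {
  variance <- match.arg(variance)
  community <- as.factor(community)
  P <- length(community)
  w <- if (is.matrix(graph)) vectorize_connectome(graph) else as.numeric(graph)
  if (length(w) != n_edges(P))
    stop("graph has ", length(w), " edges but community implies ", n_edges(P))
  block <- block_of_edges(community)
  sbm_loglik_fast(w, block, variance)
}

# core likelihood on precomputed edge weights + block ids (hot loop of the
# permutation test; everything vectorized through rowsum)
sbm_loglik_fast <- function(w, block, variance = "pooled",
                            var_floor = 1e-12) {
  E <- length(w)
  fb <- factor(block)
  n_b <- tabulate(fb)
  sum_b <- rowsum(w, fb, reorder = TRUE)[, 1]
  mu_b <- sum_b / n_b
  rss_b <- rowsum(w^2, fb, reorder = TRUE)[, 1] - n_b * mu_b^2
  degenerate <- FALSE
  if (variance == "pooled") {
    s2 <- sum(rss_b) / E
    if (s2 < var_floor) { s2 <- var_floor; degenerate <- TRUE }
    ll <- -E / 2 * log(2 * pi * s2) - sum(rss_b) / (2 * s2)
    out <- list(block_means = mu_b, sigma2 = s2, loglik = ll,
                n_edges = E, degenerate = degenerate)
  } else {
    s2_b <- rss_b / n_b
    low <- s2_b < var_floor
    if (any(low)) { s2_b[low] <- var_floor; degenerate <- TRUE }
    ll <- sum(-n_b / 2 * log(2 * pi * s2_b) - rss_b / (2 * s2_b))
    out <- list(block_means = mu_b, block_sigma2 = s2_b, loglik = ll,
                n_edges = E, degenerate = degenerate)
  }
  class(out) <- "sbm_fit"
  out
}

#' @export
print.sbm_fit <- function(x, ...) {
  cat(sprintf("sbm_fit: %d blocks, loglik = %.3f%s\n", length(x$block_means),
              x$loglik, if (x$degenerate) " (degenerate variance)" else ""))
  invisible(x)
}

#' Permutation test for community structure under the Gaussian SBM
#'
#' Null distribution built by uniformly permuting node labels while keeping
#' every community's size fixed, recomputing the profile log-likelihood per
#' permutation.  The p-value uses the add-one correction
#' p = (1 + #\{l_null >= l_obs\}) / (n_perm + 1), so it is a valid
#' finite-sample p-value and never zero.
#'
#' @inheritParams sbm_profile_loglik
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed.
#' @return object of class `sbm_test`: `loglik_obs`, `loglik_null`
#'   (n_perm values), `p_value`, `n_perm`, `seed`.
#' @export
sbm_permutation_test <- function(graph, community, n_perm = 199L, seed = 1L,
                                 variance = c("pooled", "per_block")) {
  variance <- match.arg(variance)
  if (n_perm < 1) stop("n_perm must be >= 1")
  community <- as.factor(community)
  P <- length(community)
  w <- if (is.matrix(graph)) vectorize_connectome(graph) else as.numeric(graph)
  if (length(w) != n_edges(P))
    stop("graph has ", length(w), " edges but community implies ", n_edges(P))
  obs <- sbm_loglik_fast(w, block_of_edges(community), variance)$loglik
  set.seed(seed)
  null_ll <- vapply(seq_len(n_perm), function(b) {
    zp <- community[sample.int(P)]
    sbm_loglik_fast(w, block_of_edges(zp), variance)$loglik
  }, 0)
  p <- (1 + sum(null_ll >= obs)) / (n_perm + 1)
  structure(list(loglik_obs = obs, loglik_null = null_ll, p_value = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "sbm_test")
}

#' @export
print.sbm_test <- function(x, ...) {
  cat(sprintf("sbm_test: loglik_obs = %.3f, null median = %.3f, p = %.4g (%d perms)\n",
              x$loglik_obs, stats::median(x$loglik_null), x$p_value, x$n_perm))
  invisible(x)
}

#' Bonferroni family-wise error control
#'
#' @param p_values vector of p-values in (0, 1].
#' @param alpha family-wise alpha (default 0.05).
#' @return logical vector: reject where p < alpha / m, m = number of tests.
#' @export
bonferroni_reject <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  p_values < alpha / length(p_values)
}

#' Community-structure profile across basis components
#'
#' Runs the SBM permutation test on every one of the first `k` components of
#' a basis (each devectorized to its symmetric P x P loading matrix),
#' producing the per-component structure profile: observed profile
#' log-likelihood, the null median and 95% interval, the permutation
#' p-value, and the Bonferroni decision across the k tests.
#'
#' @param basis a `basis_set`.
#' @param community node-to-community assignment of length P.
#' @param n_perm permutations per component.
#' @param seed master seed; component c uses seed + c.
#' @param k number of leading components to profile (default all).
#' @param alpha family-wise alpha for the Bonferroni decision.
#' @inheritParams sbm_profile_loglik
#' @return data.frame with columns component, loglik_obs, null_median,
#'   null_lo, null_hi, p_value, significant_bonferroni.
#' @export
component_structure_profile <- function(basis, community, n_perm = 199L,
                                        seed = 1L, k = basis$K_max,
                                        alpha = 0.05,
                                        variance = c("pooled", "per_block")) {
  stopifnot(inherits(basis, "basis_set"))
  variance <- match.arg(variance)
  community <- as.factor(community)
  if (length(community) != basis$P)
    stop("community assignment length does not match basis node count")
  k <- min(k, basis$K_max)
  rows <- vector("list", k)
  for (cc in seq_len(k)) {
    tst <- sbm_permutation_test(basis$components[, cc], community,
                                n_perm = n_perm, seed = seed + cc,
                                variance = variance)
    qs <- stats::quantile(tst$loglik_null, c(0.025, 0.5, 0.975), names = FALSE)
    rows[[cc]] <- data.frame(component = cc, loglik_obs = tst$loglik_obs,
                             null_median = qs[2], null_lo = qs[1],
                             null_hi = qs[3], p_value = tst$p_value)
  }
  out <- do.call(rbind, rows)
  out$significant_bonferroni <- bonferroni_reject(out$p_value, alpha)
  out
}
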