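#' ICC(2,1): single-measure absolute-agreement intraclass correlation
#'
#' Two-way random-effects ANOVA decomposition of an n subjects x k sessions
#' ratings table into between-subject (BMS), between-session (JMS) and
#' residual (EMS) mean squares, with
#' \deqn{ICC(2,1) = \frac{BMS - EMS}{BMS + (k-1)EMS + k(JMS - EMS)/n}.}
#'
#' @param ratings numeric n x k matrix, no missing cells.
#' @return ICC value; NA (with attribute `degenerate = TRUE`) when the table
#'   has zero total variance.
#' @export
icc_2_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 sessions")
  if (anyNA(ratings)) stop("missing cells are not supported")
  grand <- mean(ratings)
  if (all(ratings == ratings[1])) return(structure(NA_real_, degenerate = TRUE))
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  jms <- ss_cols / (k - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  denom <- bms + (k - 1) * ems + k * (jms - ems) / n
  if (denom == 0) return(structure(NA_real_, degenerate = TRUE))
  (bms - ems) / denom
}

#' Per-edge test-retest ICC
#'
#' Applies [icc_2_1()] to every edge column of a paired-session dataset.
#'
#' @param retest a `retest_dataset`.
#' @return numeric E-vector of edge ICCs (NA where degenerate).
#' @export
edge_icc <- function(retest) {
  stopifnot(inherits(retest, "retest_dataset"))
  vapply(seq_len(ncol(retest$session1)), function(e)
    as.numeric(icc_2_1(cbind(retest$session1[, e], retest$session2[, e]))),
    0)
}

#' Per-component expression-score ICC
#'
#' Computes expression scores for both sessions from a basis trained on data
#' that EXCLUDES the retest subjects, then the ICC(2,1) of each of the first
#' k score columns across sessions.
#'
#' @param basis a `basis_set`.
#' @param retest a `retest_dataset`.
#' @param k number of components.
#' @return numeric k-vector of component ICCs.
#' @export
component_icc <- function(basis, retest, k) {
  stopifnot(inherits(basis, "basis_set"), inherits(retest, "retest_dataset"))
  if (any(retest$subject_ids %in% basis$training_ids))
    stop("retest subjects overlap the basis training set")
  s1 <- session_scores(basis, retest$session1, retest$subject_ids, k)
  s2 <- session_scores(basis, retest$session2, retest$subject_ids, k)
  vapply(seq_len(k), function(cc)
    as.numeric(icc_2_1(cbind(s1[, cc], s2[, cc]))), 0)
}

session_scores <- function(basis, X, ids, k) {
  ds <- assemble_dataset(X, subject_ids = ids)
  expression_scores(basis, ds, k)$scores
}

#' Permuted-component ICC null
#'
#' Quantifies how much of the component-level ICC boost is mere aggregation
#' of edges: for each permutation, every component's E loadings are
#' independently shuffled across edge positions, expression scores are
#' recomputed for both sessions with the shuffled loadings, and the ICC of
#' each permuted component is taken.  Each permutation is summarized by the
#' mean ICC over the k components; the report gives the overall mean and the
#' [2.5, 97.5] percentile interval of the per-permutation means.
#'
#' @inheritParams component_icc
#' @param n_perm number of permutations (>= 2).
#' @param seed master seed; component c in permutation b draws from an
#'   independent substream.
#' @return object of class `icc_null`: `mean` (overall mean permuted ICC),
#'   `ci` (percentile interval of per-permutation means), `per_perm_mean`,
#'   `n_perm`, `seed`.
#' @export
permuted_component_icc <- function(basis, retest, k, n_perm = 100L, seed = 1L) {
  stopifnot(inherits(basis, "basis_set"), inherits(retest, "retest_dataset"))
  if (n_perm < 2) stop("n_perm must be >= 2")
  if (any(retest$subject_ids %in% basis$training_ids))
    stop("retest subjects overlap the basis training set")
  E <- length(basis$mean_vector)
  X1c <- sweep(retest$session1, 2, basis$mean_vector)
  X2c <- sweep(retest$session2, 2, basis$mean_vector)
  V <- basis$components[, seq_len(k), drop = FALSE]
  set.seed(seed)
  per_perm_mean <- vapply(seq_len(n_perm), function(b) {
    Vp <- apply(V, 2, function(v) v[sample.int(E)])
    s1 <- X1c %*% Vp
    s2 <- X2c %*% Vp
    iccs <- vapply(seq_len(k), function(cc)
      as.numeric(icc_2_1(cbind(s1[, cc], s2[, cc]))), 0)
    mean(iccs, na.rm = TRUE)
  }, 0)
  structure(
    list(mean = mean(per_perm_mean),
         ci = stats::quantile(per_perm_mean, c(0.025, 0.975), names = FALSE),
         per_perm_mean = per_perm_mean,
         n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "icc_null")
}

#' @export
print.icc_null <- function(x, ...) {
  cat(sprintf("icc_null: mean permuted-component ICC %.4f (95%% CI %.4f-%.4f, %d perms)\n",
              x$mean, x$ci[1], x$ci[2], x$n_perm))
  invisible(x)
}

#' Full test-retest reliability report
#'
#' Convenience wrapper producing per-edge ICCs, per-component ICCs for the
#' first k components, and the permuted-component null in one object.
#'
#' @inheritParams permuted_component_icc
#' @return object of class `icc_report`: `edge_icc`, `component_icc`,
#'   `mean_edge_icc`, `mean_component_icc`, `null`.
#' @export
icc_report <- function(basis, retest, k, n_perm = 100L, seed = 1L) {
  ei <- edge_icc(retest)
  ci <- component_icc(basis, retest, k)
  nul <- permuted_component_icc(basis, retest, k, n_perm = n_perm, seed = seed)
  structure(
    list(edge_icc = ei, component_icc = ci,
         mean_edge_icc = mean(ei, na.rm = TRUE),
         mean_component_icc = mean(ci, na.rm = TRUE),
         n_missing_edges = sum(is.na(ei)),
         null = nul),
    class = "icc_report")
}

#' @export
print.icc_report <- function(x, ...) {
  cat(sprintf("icc_report: mean edge ICC %.3f, mean component ICC %.3f\n",
              x$mean_edge_icc, x$mean_component_icc))
  cat(sprintf("  permuted-component null mean %.4f (95%% CI %.4f-%.4f)\n",
              x$null$mean, x$null$ci[1], x$null$ci[2]))
  invisible(x)
}
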