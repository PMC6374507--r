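#' Fit the PCA basis of inter-individual connectome variation
#'
#' Principal component analysis of the subjects x edges matrix via the thin
#' (economy) route: because the number of edges E vastly exceeds the number
#' of subjects N, the N x N Gram matrix of the centered data is
#' eigendecomposed and loadings are recovered as X_c' U / sqrt(l), avoiding
#' the E x E covariance entirely.  Eigenvalues are variances (Gram
#' eigenvalues divided by N - 1) and sum to the total variance of the
#' centered data.  Component sign is fixed so each column's
#' largest-magnitude loading is positive.
#'
#' @param train a `connectome_dataset` (N >= 2 subjects).
#' @return object of class `basis_set`: `mean_vector` (E), `components`
#'   (E x K_max orthonormal loadings, descending eigenvalue order),
#'   `eigenvalues` (length N - 1, zeros beyond the data rank), `K_max`,
#'   `training_N`, `P`, `edge_index`, `training_ids`, `id` (provenance hash).
#' @export
fit_pca <- function(train) {
  stopifnot(inherits(train, "connectome_dataset"))
  X <- train$X
  N <- nrow(X)
  if (N < 2) stop("need at least 2 subjects")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total_var <- sum(Xc^2) / (N - 1)
  if (total_var == 0) stop("constant dataset: no variation to decompose")
  G <- tcrossprod(Xc)                      # N x N
  e <- eigen(G, symmetric = TRUE)
  lam_gram <- pmax(e$values[seq_len(N - 1)], 0)
  eigenvalues <- lam_gram / (N - 1)
  keep <- which(lam_gram > max(lam_gram) * 1e-12)
  U <- e$vectors[, keep, drop = FALSE]
  V <- crossprod(Xc, U)                    # E x K
  V <- sweep(V, 2, sqrt(lam_gram[keep]), "/")
  # sign convention: largest-magnitude loading positive
  flip <- vapply(seq_len(ncol(V)), function(k) {
    v <- V[, k]
    sign(v[which.max(abs(v))])
  }, 0)
  V <- sweep(V, 2, flip, "*")
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  structure(
    list(mean_vector = mu, components = V, eigenvalues = eigenvalues,
         K_max = ncol(V), training_N = N, P = train$P,
         edge_index = train$edge_index, training_ids = train$subject_ids,
         id = paste0("pca-", N, "x", ncol(X), "-", ncol(V))),
    class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat("basis_set:", x$K_max, "components from", x$training_N, "subjects (",
      length(x$mean_vector), "edges )\n")
  invisible(x)
}

#' Component expression scores
#'
#' Projects each subject's connectome onto the first k components after
#' centering by the TRAINING mean (also for test data: the out-of-sample
#' contract never uses test-set statistics).
#'
#' @param basis a `basis_set`.
#' @param dataset a `connectome_dataset` with the same edge convention.
#' @param k number of components (1 <= k <= K_max).
#' @return object of class `expression_scores`: `scores` (N x k),
#'   `subject_ids`, `k`, `basis_id`.
#' @export
expression_scores <- function(basis, dataset, k = basis$K_max) {
  stopifnot(inherits(basis, "basis_set"), inherits(dataset, "connectome_dataset"))
  if (ncol(dataset$X) != length(basis$mean_vector))
    stop("dataset edge count does not match basis")
  if (k < 1 || k > basis$K_max) stop("k must be in 1..K_max = ", basis$K_max)
  Xc <- sweep(dataset$X, 2, basis$mean_vector)
  S <- Xc %*% basis$components[, seq_len(k), drop = FALSE]
  rownames(S) <- dataset$subject_ids
  structure(list(scores = S, subject_ids = dataset$subject_ids,
                 k = as.integer(k), basis_id = basis$id),
            class = "expression_scores")
}

#' Reconstruct connectomes from a k-component basis
#'
#' X_hat = mean + scores t(components[, 1:k]).  With orthonormal components
#' this equals the least-squares fit of each subject's edge vector on the k
#' components plus intercept (multiple regression).
#'
#' @inheritParams expression_scores
#' @return N x E matrix of reconstructed edge vectors (k = 0 gives every
#'   subject the training mean).
#' @export
reconstruct <- function(basis, dataset, k) {
  stopifnot(inherits(basis, "basis_set"), inherits(dataset, "connectome_dataset"))
  if (k == 0) {
    R <- matrix(basis$mean_vector, nrow(dataset$X), length(basis$mean_vector),
                byrow = TRUE)
    rownames(R) <- dataset$subject_ids
    return(R)
  }
  sc <- expression_scores(basis, dataset, k)
  R <- sc$scores %*% t(basis$components[, seq_len(k), drop = FALSE])
  R <- sweep(R, 2, basis$mean_vector, "+")
  rownames(R) <- dataset$subject_ids
  R
}

#' Out-of-sample reconstruction curve
#'
#' For each basis size k in `k_grid`, reconstructs every subject in
#' `dataset` and computes the Pearson correlation across edges between the
#' actual and reconstructed edge vectors (raw vectors, not edge-centered:
#' the shared mean edge vector contributes, which inflates the baseline at
#' small k).  Reports the mean across subjects with a normal-approximation
#' 95% CI.
#'
#' @inheritParams expression_scores
#' @param k_grid integer vector of basis sizes (0 allowed).
#' @return object of class `reconstruction_curve`: data.frame `curve` with
#'   columns k, mean_r, ci_lo, ci_hi, n_missing; matrix `per_subject`
#'   (subjects x k values).
#' @export
reconstruction_curve <- function(basis, dataset, k_grid) {
  stopifnot(inherits(basis, "basis_set"), inherits(dataset, "connectome_dataset"))
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 0 | k_grid > basis$K_max)) stop("k_grid must lie in 0..K_max")
  N <- nrow(dataset$X)
  per_subject <- matrix(NA_real_, N, length(k_grid),
                        dimnames = list(dataset$subject_ids, k_grid))
  for (a in seq_along(k_grid)) {
    R <- reconstruct(basis, dataset, k_grid[a])
    for (i in seq_len(N)) {
      x <- dataset$X[i, ]
      y <- R[i, ]
      if (stats::sd(y) == 0 || stats::sd(x) == 0) {
        warning("degenerate reconstruction for subject ", i, " at k = ",
                k_grid[a], "; correlation recorded as missing")
        next
      }
      per_subject[i, a] <- stats::cor(x, y)
    }
  }
  mean_r <- colMeans(per_subject, na.rm = TRUE)
  n_ok <- colSums(!is.na(per_subject))
  se <- apply(per_subject, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1))
  curve <- data.frame(k = k_grid, mean_r = mean_r,
                      ci_lo = mean_r - 1.96 * se, ci_hi = mean_r + 1.96 * se,
                      n_missing = N - n_ok, row.names = NULL)
  structure(list(curve = curve, per_subject = per_subject),
            class = "reconstruction_curve")
}

#' @export
print.reconstruction_curve <- function(x, ...) {
  cat("reconstruction_curve over", nrow(x$curve), "basis sizes\n")
  print(utils::head(x$curve, 10))
  invisible(x)
}
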