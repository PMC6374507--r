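#' Edge index for a P-node connectome
#'
#' The package uses a single frozen edge ordering everywhere: the upper
#' triangle of the symmetric connectivity matrix traversed row-major, i.e.
#' node pairs (i, j) with i < j ordered first by i then by j, 0-based.
#' For P nodes this yields E = P(P-1)/2 edges.
#'
#' @param P number of nodes.
#' @return data.frame with 0-based columns `i`, `j` and a `name` column
#'   formatted `"i_j"`, one row per edge in canonical order.
#' @export
edge_index <- function(P) {
  stopifnot(is.numeric(P), length(P) == 1, P >= 2)
  P <- as.integer(P)
  i <- rep.int(0:(P - 2L), times = (P - 1L):1L)
  j <- unlist(lapply(0:(P - 2L), function(a) (a + 1L):(P - 1L)), use.names = FALSE)
  data.frame(i = i, j = j, name = paste0(i, "_", j), stringsAsFactors = FALSE)
}

#' Number of unique edges for P nodes
#' @param P number of nodes.
#' @return integer E = P(P-1)/2.
#' @export
n_edges <- function(P) as.integer(P * (P - 1) / 2)

#' Pearson correlation matrix of an ROI time-series matrix
#'
#' @param ts numeric matrix, T timepoints x P nodes.  Column names, if
#'   present, are carried over as node ids.
#' @return P x P symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time series must be numeric")
  if (nrow(ts) < 3) stop("need at least 3 timepoints")
  if (anyNA(ts)) stop("time series contains missing values")
  v <- apply(ts, 2, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    nm <- colnames(ts)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("zero-variance node column(s): ", paste(nm, collapse = ", "))
  }
  r <- stats::cor(ts)
  # guard against numerical drift outside [-1, 1]
  r[r > 1] <- 1
  r[r < -1] <- -1
  0.5 * (r + t(r))
}

#' Fisher r-to-z transform
#'
#' z = atanh(r) = 0.5 log((1+r)/(1-r)).  Entries with |r| >= 1 are an error
#' by default because they map to +/- infinity; `clip = TRUE` instead clips
#' them to +/-(1 - 1e-7) with a warning (useful for degenerate synthetic
#' configurations).
#'
#' @param r correlation value, vector or matrix.
#' @param clip clip |r| >= 1 instead of erroring.
#' @return transformed values, same shape as `r`.
#' @export
fisher_z <- function(r, clip = FALSE) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    if (!clip) stop("|r| >= 1 encountered; atanh is infinite (use clip = TRUE to clip)")
    warning("clipping ", sum(abs(r) >= 1), " correlation(s) with |r| >= 1")
    lim <- 1 - 1e-7
    r[r >= 1] <- lim
    r[r <= -1] <- -lim
  }
  atanh(r)
}

#' Fisher-z connectome from a time-series matrix
#'
#' Pearson correlations followed by the Fisher transform on off-diagonal
#' entries; the diagonal is set to 0 and excluded from all analyses.
#'
#' @inheritParams pearson_matrix
#' @param clip passed to [fisher_z()].
#' @return P x P symmetric matrix of Fisher-z values, zero diagonal.
#' @export
z_connectome <- function(ts, clip = FALSE) {
  r <- pearson_matrix(ts)
  diag(r) <- 0
  z <- fisher_z(r, clip = clip)
  diag(z) <- 0
  dimnames(z) <- list(colnames(ts), colnames(ts))
  z
}

#' Vectorize / devectorize a connectome
#'
#' `vectorize_connectome` extracts the E = P(P-1)/2 unique edges of a
#' symmetric matrix in the canonical [edge_index()] order;
#' `devectorize_connectome` inverts it, producing a symmetric matrix with
#' zero diagonal.
#'
#' @param m symmetric P x P matrix.
#' @return numeric E-vector.
#' @export
vectorize_connectome <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("connectome matrix must be square")
  if (max(abs(m - t(m))) > 1e-12 * max(1, max(abs(m))))
    stop("connectome matrix must be symmetric")
  # row-major upper triangle of m == column-major lower triangle
  m[lower.tri(m)]
}

#' @rdname vectorize_connectome
#' @param v edge vector of triangular length.
#' @param P number of nodes; inferred from `length(v)` if missing.
#' @export
devectorize_connectome <- function(v, P = NULL) {
  E <- length(v)
  if (is.null(P)) P <- (1 + sqrt(1 + 8 * E)) / 2
  if (abs(P - round(P)) > 1e-8 || n_edges(round(P)) != E)
    stop("vector length ", E, " is not a triangular number matching P")
  P <- as.integer(round(P))
  m <- matrix(0, P, P)
  m[lower.tri(m)] <- v
  m + t(m)
}

#' Assemble a subjects x edges connectome dataset
#'
#' The central container of the pipeline: an N x E matrix of Fisher-z edge
#' values, one row per subject, columns in the canonical edge order.
#'
#' @param connectomes list of symmetric P x P Fisher-z matrices sharing node
#'   ids, or an already-vectorized N x E matrix.
#' @param subject_ids character vector of unique subject ids.
#' @param node_ids optional node labels (length P).
#' @return object of class `connectome_dataset` with elements `X` (N x E),
#'   `subject_ids`, `node_ids`, `P`, `edge_index`.
#' @export
assemble_dataset <- function(connectomes, subject_ids = NULL, node_ids = NULL) {
  if (is.matrix(connectomes)) {
    X <- connectomes
    E <- ncol(X)
    P <- (1 + sqrt(1 + 8 * E)) / 2
    if (abs(P - round(P)) > 1e-8) stop("column count is not a triangular number")
    P <- as.integer(round(P))
  } else {
    if (!length(connectomes)) stop("no connectomes supplied")
    P <- nrow(connectomes[[1]])
    nid <- dimnames(connectomes[[1]])[[1]]
    for (m in connectomes) {
      if (nrow(m) != P) stop("all connectomes must share the same node set")
      if (!identical(dimnames(m)[[1]], nid)) stop("mismatched node ids across connectomes")
    }
    if (is.null(node_ids)) node_ids <- nid
    X <- t(vapply(connectomes, vectorize_connectome, numeric(n_edges(P))))
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%04d", seq_len(nrow(X)))
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  if (length(subject_ids) != nrow(X)) stop("subject_ids length does not match rows")
  if (is.null(node_ids)) node_ids <- sprintf("node%03d", seq_len(P))
  ei <- edge_index(P)
  colnames(X) <- ei$name
  rownames(X) <- subject_ids
  structure(
    list(X = X, subject_ids = subject_ids, node_ids = node_ids,
         P = P, edge_index = ei),
    class = "connectome_dataset")
}

#' @export
print.connectome_dataset <- function(x, ...) {
  cat("connectome_dataset:", nrow(x$X), "subjects x", ncol(x$X),
      "edges (P =", x$P, "nodes)\n")
  invisible(x)
}

#' @export
dim.connectome_dataset <- function(x) dim(x$X)

#' Subset a connectome dataset by subjects
#' @param ds a `connectome_dataset`.
#' @param idx integer or logical subject index, or character subject ids.
#' @return a `connectome_dataset` restricted to the selected subjects.
#' @export
subset_subjects <- function(ds, idx) {
  stopifnot(inherits(ds, "connectome_dataset"))
  if (is.character(idx)) idx <- match(idx, ds$subject_ids)
  ds$X <- ds$X[idx, , drop = FALSE]
  ds$subject_ids <- ds$subject_ids[idx]
  ds
}

#' Split a connectome dataset into training and held-out test sets
#'
#' Subjects are drawn at random without replacement; the split is seeded and
#' reproducible, disjoint and exhaustive.
#'
#' @param ds a `connectome_dataset`.
#' @param n_test number of held-out subjects (0 < n_test < N).
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both `connectome_dataset`s.
#' @export
split_train_test <- function(ds, n_test, seed = 1L) {
  stopifnot(inherits(ds, "connectome_dataset"))
  N <- nrow(ds$X)
  if (n_test <= 0 || n_test >= N) stop("need 0 < n_test < N")
  set.seed(seed)
  test_idx <- sort(sample.int(N, n_test))
  list(train = subset_subjects(ds, setdiff(seq_len(N), test_idx)),
       test = subset_subjects(ds, test_idx))
}
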