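#' Fit a Brain Basis Set (BBS) model
#'
#' Ordinary least squares of the phenotype on k component expression scores,
#' with intercept.  The coefficient vector B is applied to new subjects'
#' scores by [predict_bbs()].
#'
#' @param scores an `expression_scores` object (training subjects).
#' @param phenotype numeric vector, one value per training subject.
#' @param intercept include an intercept (default TRUE; correlation-based
#'   evaluation is intercept-invariant but absolute predictions are not).
#' @return object of class `bbs_model`: `B` (k coefficients), `intercept`,
#'   `k`, `basis_id`.
#' @export
fit_bbs <- function(scores, phenotype, intercept = TRUE) {
  stopifnot(inherits(scores, "expression_scores"))
  y <- as.numeric(phenotype)
  S <- scores$scores
  if (length(y) != nrow(S)) stop("phenotype length does not match scores")
  if (anyNA(y)) stop("missing phenotype values")
  if (nrow(S) <= ncol(S) + 1) stop("need N > k + 1 subjects")
  D <- if (intercept) cbind(`(Intercept)` = 1, S) else S
  qr_D <- qr(D)
  if (qr_D$rank < ncol(D)) stop("rank-deficient design matrix")
  beta <- qr.coef(qr_D, y)
  structure(
    list(B = if (intercept) beta[-1] else beta,
         intercept = if (intercept) unname(beta[1]) else 0,
         k = scores$k, basis_id = scores$basis_id),
    class = "bbs_model")
}

#' Predict phenotypes from a BBS model
#'
#' y_hat = intercept + scores . B, using expression scores computed from the
#' same basis and k as the training partition.
#'
#' @param model a `bbs_model`.
#' @param scores an `expression_scores` object for the test subjects.
#' @return numeric vector of predictions.
#' @export
predict_bbs <- function(model, scores) {
  stopifnot(inherits(model, "bbs_model"), inherits(scores, "expression_scores"))
  if (!identical(model$basis_id, scores$basis_id))
    stop("scores come from a different basis than the model")
  if (scores$k != model$k) stop("scores use k = ", scores$k,
                                " but model was fitted with k = ", model$k)
  drop(model$intercept + scores$scores %*% model$B)
}

#' Cross-validated BBS plateau curves
#'
#' 10-fold (by default) cross-validation within the training set.  Fold
#' assignment is a seeded random partition.  Within each fold the PCA basis
#' is re-learned on the fold-training subjects only (no leakage of held-out
#' subjects into the component definitions); BBS models are fitted for every
#' k in `k_grid` and evaluated by the Pearson correlation between actual and
#' predicted phenotype on the held-out fold.  The curve is the mean across
#' folds per k, with a fold-spread 95% CI.
#'
#' @param train a `connectome_dataset`.
#' @param phenotypes numeric vector or single-phenotype data.frame column,
#'   aligned with the dataset's subjects.
#' @param k_grid basis sizes to evaluate.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed for the fold partition.
#' @return object of class `cv_curve`: data.frame `curve` (k, mean_r, ci_lo,
#'   ci_hi), matrix `per_fold` (folds x k), `fold_id` assignment vector, and
#'   `predictions` (subjects x k matrix of held-out-fold predictions, each
#'   produced by a model that never saw that subject).
#' @export
crossval_bbs <- function(train, phenotypes, k_grid, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(train, "connectome_dataset"))
  y <- as.numeric(phenotypes)
  N <- nrow(train$X)
  if (length(y) != N) stop("phenotype length does not match dataset")
  if (n_folds < 2) stop("need at least 2 folds")
  if (N < 2 * n_folds) stop("need N >= 2 * n_folds")
  k_grid <- sort(unique(as.integer(k_grid)))
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(n_folds), N))
  per_fold <- matrix(NA_real_, n_folds, length(k_grid),
                     dimnames = list(NULL, k_grid))
  predictions <- matrix(NA_real_, N, length(k_grid),
                        dimnames = list(train$subject_ids, k_grid))
  for (f in seq_len(n_folds)) {
    tr <- subset_subjects(train, fold_id != f)
    te <- subset_subjects(train, fold_id == f)
    y_tr <- y[fold_id != f]
    y_te <- y[fold_id == f]
    bas <- fit_pca(tr)
    for (a in seq_along(k_grid)) {
      k <- k_grid[a]
      if (k >= nrow(tr$X) - 1 || k > bas$K_max) {
        warning("k = ", k, " too large for fold-training N = ", nrow(tr$X),
                "; skipped")
        next
      }
      sc_tr <- expression_scores(bas, tr, k)
      sc_te <- expression_scores(bas, te, k)
      m <- fit_bbs(sc_tr, y_tr)
      pred <- predict_bbs(m, sc_te)
      predictions[fold_id == f, a] <- pred
      if (stats::sd(pred) > 0 && stats::sd(y_te) > 0)
        per_fold[f, a] <- stats::cor(y_te, pred)
    }
  }
  mean_r <- colMeans(per_fold, na.rm = TRUE)
  n_ok <- colSums(!is.na(per_fold))
  se <- apply(per_fold, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1))
  curve <- data.frame(k = k_grid, mean_r = mean_r,
                      ci_lo = mean_r - 1.96 * se, ci_hi = mean_r + 1.96 * se,
                      row.names = NULL)
  structure(list(curve = curve, per_fold = per_fold, fold_id = fold_id,
                 predictions = predictions),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat("cv_curve:", nrow(x$per_fold), "folds over", nrow(x$curve), "basis sizes\n")
  print(utils::head(x$curve, 10))
  invisible(x)
}

#' Fit a connectome predictive model (CPM)
#'
#' Selects edges whose Pearson correlation with the phenotype is significant
#' below `p_threshold` (two-sided exact t p-values) with the sign matching
#' `tail`; each subject's masked edge weights are summed and the phenotype
#' regressed on the sum (slope + intercept).  An empty mask yields a model
#' flagged degenerate whose predictions are the training-mean phenotype.
#'
#' @param train a `connectome_dataset` (N >= 10 subjects).
#' @param phenotype numeric vector aligned with the dataset.
#' @param p_threshold edge-selection significance threshold (default 0.01).
#' @param tail `"positive"` (default) or `"negative"` edge set.
#' @return object of class `cpm_model`: `edge_mask` (logical E), `slope`,
#'   `intercept`, `tail`, `p_threshold`, `degenerate`, `train_mean`.
#' @export
fit_cpm <- function(train, phenotype, p_threshold = 0.01,
                    tail = c("positive", "negative")) {
  stopifnot(inherits(train, "connectome_dataset"))
  tail <- match.arg(tail)
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0,1)")
  y <- as.numeric(phenotype)
  N <- nrow(train$X)
  if (length(y) != N) stop("phenotype length does not match dataset")
  if (N < 10) stop("need at least 10 subjects")
  r <- drop(stats::cor(train$X, y))
  r[is.na(r)] <- 0                        # constant edges never selected
  tt <- r * sqrt((N - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * stats::pt(-abs(tt), df = N - 2)
  mask <- p < p_threshold & (if (tail == "positive") r > 0 else r < 0)
  if (!any(mask)) {
    warning("no edges selected; CPM model is degenerate and predicts the ",
            "training mean")
    return(structure(list(edge_mask = mask, slope = NA_real_,
                          intercept = NA_real_, tail = tail,
                          p_threshold = p_threshold, degenerate = TRUE,
                          train_mean = mean(y)),
                     class = "cpm_model"))
  }
  sums <- rowSums(train$X[, mask, drop = FALSE])
  fit <- stats::lm.fit(cbind(1, sums), y)
  structure(
    list(edge_mask = mask, slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]), tail = tail,
         p_threshold = p_threshold, degenerate = FALSE, train_mean = mean(y)),
    class = "cpm_model")
}

#' Predict phenotypes from a CPM model
#'
#' Test-subject masked-edge sums multiplied by the fitted slope plus
#' intercept; a degenerate (empty-mask) model predicts the training mean.
#'
#' @param model a `cpm_model`.
#' @param dataset a `connectome_dataset`.
#' @return numeric vector of predictions.
#' @export
predict_cpm <- function(model, dataset) {
  stopifnot(inherits(model, "cpm_model"), inherits(dataset, "connectome_dataset"))
  if (length(model$edge_mask) != ncol(dataset$X))
    stop("edge count mismatch between model and dataset")
  if (model$degenerate)
    return(rep(model$train_mean, nrow(dataset$X)))
  sums <- rowSums(dataset$X[, model$edge_mask, drop = FALSE])
  model$intercept + model$slope * sums
}

#' Residualize phenotypes on confound variables
#'
#' OLS residuals of each phenotype column on the confound matrix plus
#' intercept; residuals are orthogonal to every confound column.
#'
#' @param phenotypes numeric vector or matrix/data.frame of phenotypes.
#' @param confounds numeric matrix/data.frame of confounds (no intercept
#'   column; one is added).
#' @return adjusted phenotypes, same shape as the input.
#' @export
residualize_phenotypes <- function(phenotypes, confounds) {
  Y <- as.matrix(phenotypes)
  Cf <- cbind(`(Intercept)` = 1, as.matrix(confounds))
  if (nrow(Y) != nrow(Cf)) stop("phenotypes and confounds differ in rows")
  qr_C <- qr(Cf)
  if (qr_C$rank < ncol(Cf)) {
    collinear <- colnames(Cf)[qr_C$pivot[(qr_C$rank + 1):ncol(Cf)]]
    stop("confound matrix is rank deficient; collinear column(s): ",
         paste(collinear, collapse = ", "))
  }
  res <- qr.resid(qr_C, Y)
  if (is.vector(phenotypes)) drop(res) else res
}

#' Compare two prediction methods sharing the same criterion
#'
#' Computes r_a = cor(actual, pred_a), r_b = cor(actual, pred_b), their
#' difference, and Steiger's z test for the difference between two dependent
#' correlations sharing the variable `actual` (accounting for the
#' inter-prediction correlation r_ab).
#'
#' @param actual criterion vector (length >= 10).
#' @param pred_a,pred_b prediction vectors from the two methods.
#' @return data.frame with r_a, r_b, diff, r_ab, z, p_value, n (p_value is
#'   NA when a prediction is constant).
#' @export
compare_methods <- function(actual, pred_a, pred_b) {
  n <- length(actual)
  if (length(pred_a) != n || length(pred_b) != n) stop("length mismatch")
  if (n < 10) stop("need at least 10 observations")
  if (stats::sd(pred_a) == 0 || stats::sd(pred_b) == 0 || stats::sd(actual) == 0) {
    warning("constant vector: comparison test undefined")
    return(data.frame(r_a = NA_real_, r_b = NA_real_, diff = NA_real_,
                      r_ab = NA_real_, z = NA_real_, p_value = NA_real_, n = n))
  }
  r_a <- stats::cor(actual, pred_a)
  r_b <- stats::cor(actual, pred_b)
  r_ab <- stats::cor(pred_a, pred_b)
  if (isTRUE(all.equal(pred_a, pred_b))) {
    return(data.frame(r_a = r_a, r_b = r_b, diff = 0, r_ab = 1, z = 0,
                      p_value = 1, n = n))
  }
  # Steiger (1980): z-test via Fisher z with pooled determination
  z_a <- atanh(r_a)
  z_b <- atanh(r_b)
  rm2 <- (r_a^2 + r_b^2) / 2
  f <- min((1 - r_ab) / (2 * (1 - rm2)), 1)
  h <- (1 - f * rm2) / (1 - rm2)
  z <- (z_a - z_b) * sqrt((n - 3) / (2 * (1 - r_ab) * h))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(r_a = r_a, r_b = r_b, diff = r_a - r_b, r_ab = r_ab,
             z = z, p_value = p, n = n)
}
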