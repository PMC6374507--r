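#' Read and write pipeline file formats
#'
#' All on-disk artifacts are delimited text (TSV/CSV) with JSON sidecars so
#' every file is diff-able and portable.  Numeric round-trips use 15
#' significant digits.
#'
#' @name connbasis-io
NULL

fmt_num <- function(x) sprintf("%.17g", x)   # exact double round-trip

#' Write / read a per-session time-series matrix (TSV, header = node ids)
#' @param ts T x P numeric matrix with node-id column names.
#' @param path file path.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !is.null(colnames(ts)))
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) stop("empty or missing file: ", path)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  if (!is.numeric(m)) stop("non-numeric values in time series file ", path)
  if (anyNA(m)) stop("missing values in time series file ", path)
  m
}

#' Write / read a node-community table (TSV: node_id, community)
#' @param node_ids node labels.
#' @param community community labels, aligned with `node_ids`.
#' @param path file path.
#' @export
write_nodes <- function(node_ids, community, path) {
  utils::write.table(
    data.frame(node_id = node_ids, community = as.character(community)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nodes
#' @return `read_nodes`: data.frame with columns node_id, community.
#' @export
read_nodes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("node_id", "community") %in% names(df)))
    stop("nodes file must have columns node_id, community")
  df
}

#' Write / read a connectome dataset (subjects x edges TSV + JSON sidecar)
#'
#' The TSV has a `subject_id` column followed by one column per edge named
#' `"i_j"`; the sidecar records P, the edge-ordering convention, and
#' provenance, and is checked on read.
#'
#' @param ds a `connectome_dataset`.
#' @param path TSV path; the sidecar is `paste0(path, ".json")`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "connectome_dataset"))
  df <- data.frame(subject_id = ds$subject_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(apply(ds$X, 2, fmt_num)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(P = ds$P, n_subjects = length(ds$subject_ids),
               edge_order = "upper-triangle row-major, i<j, 0-based",
               node_ids = ds$node_ids, package = "connbasis")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar for ", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  if (ncol(X) != n_edges(meta$P))
    stop("edge count in ", path, " disagrees with sidecar P = ", meta$P)
  expected <- edge_index(meta$P)$name
  if (!identical(colnames(X), expected))
    stop("edge column order in ", path, " does not match the canonical convention")
  assemble_dataset(X, subject_ids = as.character(df[[1]]),
                   node_ids = meta$node_ids)
}

#' Write / read a basis bundle (loadings, eigenvalues, mean + JSON metadata)
#'
#' @param basis a `basis_set`.
#' @param dir output directory (created if needed).
#' @param k_keep number of leading components to store (default all).
#' @export
write_basis <- function(basis, dir, k_keep = basis$K_max) {
  stopifnot(inherits(basis, "basis_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  V <- basis$components[, seq_len(k_keep), drop = FALSE]
  ld <- data.frame(edge = basis$edge_index$name, apply(V, 2, fmt_num),
                   check.names = FALSE)
  utils::write.table(ld, file.path(dir, "loadings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(eigenvalue = fmt_num(basis$eigenvalues)),
                     file.path(dir, "eigenvalues.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(edge = basis$edge_index$name,
                                mean = fmt_num(basis$mean_vector)),
                     file.path(dir, "mean.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(P = basis$P, training_N = basis$training_N, K_max = basis$K_max,
         k_stored = k_keep, id = basis$id,
         training_ids = basis$training_ids,
         edge_order = "upper-triangle row-major, i<j, 0-based"),
    file.path(dir, "basis.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_basis
#' @export
read_basis <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "basis.json"), simplifyVector = TRUE)
  ld <- utils::read.table(file.path(dir, "loadings.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  V <- as.matrix(ld[, -1, drop = FALSE]); storage.mode(V) <- "double"
  ev <- utils::read.table(file.path(dir, "eigenvalues.tsv"), header = TRUE,
                          sep = "\t")$eigenvalue
  mu <- utils::read.table(file.path(dir, "mean.tsv"), header = TRUE,
                          sep = "\t")$mean
  ei <- edge_index(meta$P)
  mu <- as.numeric(mu)
  names(mu) <- ei$name
  rownames(V) <- NULL
  structure(
    list(mean_vector = mu, components = V,
         eigenvalues = as.numeric(ev), K_max = ncol(V),
         training_N = meta$training_N, P = meta$P,
         edge_index = ei, training_ids = meta$training_ids,
         id = meta$id),
    class = "basis_set")
}

#' Read / validate a pipeline configuration (YAML)
#'
#' The config is a nested key-value document holding every stage's
#' parameters; unknown top-level keys are rejected and all seeds must be
#' explicit.
#'
#' @param path YAML file path, or a list already in memory.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  allowed <- c("simulation", "split", "dimensionality", "basis",
               "prediction", "network", "reliability", "out_dir", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  required <- c("simulation", "out_dir", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) stop("missing config key(s): ", paste(missing, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

default_pipeline_config <- function(out_dir, seed = 1L) {
  list(
    simulation = list(n_subjects = 120, n_nodes = 40, n_communities = 4,
                      n_components = 5,
                      eigen_spectrum = c(1, 0.9, 0.8, 0.7, 0.6),
                      mean_connectome_scale = 0.3, edge_noise_sd = 0.05,
                      timepoints_min = 120, timepoints_max = 150,
                      n_phenotypes = 1,
                      phenotype_coefficients = c(1, 1, 1, 0, 0),
                      phenotype_noise_sd = 1),
    split = list(n_test = 30),
    dimensionality = list(k1 = 10, k2 = 20, n_perm = 10),
    basis = list(k_grid = c(1, 2, 5, 10, 20), k = 5),
    prediction = list(k_grid = c(1, 2, 5, 10), n_folds = 5,
                      cpm_p_threshold = 0.01),
    network = list(n_perm = 99, n_components = 5, alpha = 0.05),
    reliability = list(k = 5, n_perm = 50, session_noise_sd = 0.1),
    out_dir = out_dir, seed = seed)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains every stage in order: simulate -> connectomes -> train/test split
#' -> intrinsic dimensionality + ROI-swap null -> PCA basis + out-of-sample
#' reconstruction -> cross-validated BBS plateau -> BBS vs CPM on the
#' held-out split -> SBM community-structure profile -> test-retest
#' reliability.  All outputs are delimited text under `out_dir`, and a run
#' manifest (config hash, per-stage output checksums) is written and
#' returned; re-running with an identical config reproduces identical
#' checksums.
#'
#' @param config a `pipeline_config`, a YAML path, or a plain list; see
#'   [read_pipeline_config()].
#' @return the manifest list, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  sm <- cfg$simulation
  scfg <- sim_config(
    n_subjects = sm$n_subjects,
    community_assignment = even_communities(sm$n_nodes, sm$n_communities),
    n_components = sm$n_components,
    eigen_spectrum = sm$eigen_spectrum,
    mean_connectome_scale = sm$mean_connectome_scale,
    edge_noise_sd = sm$edge_noise_sd,
    timepoints_range = c(sm$timepoints_min, sm$timepoints_max),
    n_phenotypes = sm$n_phenotypes,
    phenotype_coefficients = matrix(sm$phenotype_coefficients,
                                    ncol = sm$n_phenotypes),
    phenotype_noise_sd = sm$phenotype_noise_sd,
    retest = TRUE, seed = seed)
  stages <- list()
  message("[simulate] N = ", scfg$n_subjects, ", P = ", scfg$P)
  sim <- simulate_subjects(scfg)
  phen <- simulate_phenotypes(sim)
  write_nodes(sim$node_ids, scfg$community_assignment,
              file.path(out, "nodes.tsv"))
  utils::write.csv(phen, file.path(out, "phenotypes.csv"), row.names = FALSE)
  stages$simulate <- c("nodes.tsv", "phenotypes.csv")

  message("[connectome] building Fisher-z dataset")
  ds <- observed_dataset(sim)
  write_dataset(ds, file.path(out, "connectomes.tsv"))
  stages$connectome <- "connectomes.tsv"

  sp <- split_train_test(ds, cfg$split$n_test, seed = seed + 10L)
  train <- sp$train; test <- sp$test
  y <- phen[[2]][match(train$subject_ids, phen$subject_id)]
  y_test <- phen[[2]][match(test$subject_ids, phen$subject_id)]

  message("[dimensionality] Levina-Bickel + ROI-swap null")
  dm <- cfg$dimensionality
  lb <- levina_bickel(train$X, k1 = dm$k1, k2 = dm$k2)
  nul <- roi_swap_null(sim$time_series, n_perm = dm$n_perm, seed = seed + 20L)
  jsonlite::write_json(list(m_hat = lb$m_hat, per_k = lb$per_k,
                            k1 = lb$k1, k2 = lb$k2),
                       file.path(out, "dimensionality.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(round(nul$null_percents, 6),
                     file.path(out, "null_spectrum.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = paste0("PC", seq_along(nul$observed_percents)))
  stages$dimensionality <- c("dimensionality.json", "null_spectrum.tsv")

  message("[basis] PCA + reconstruction curve")
  bas <- fit_pca(train)
  write_basis(bas, file.path(out, "basis"), k_keep = min(bas$K_max, 50L))
  rc <- reconstruction_curve(bas, test, cfg$basis$k_grid)
  utils::write.table(rc$curve, file.path(out, "reconstruction_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages$basis <- c("basis/basis.json", "reconstruction_curve.tsv")

  message("[prediction] CV plateau + BBS vs CPM")
  pr <- cfg$prediction
  cv <- crossval_bbs(train, y, pr$k_grid, n_folds = pr$n_folds,
                     seed = seed + 30L)
  utils::write.table(cv$curve, file.path(out, "cv_plateau.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  k_bbs <- cfg$basis$k
  m_bbs <- fit_bbs(expression_scores(bas, train, k_bbs), y)
  pred_bbs <- predict_bbs(m_bbs, expression_scores(bas, test, k_bbs))
  m_cpm <- fit_cpm(train, y, p_threshold = pr$cpm_p_threshold)
  pred_cpm <- predict_cpm(m_cpm, test)
  cmp <- compare_methods(y_test, pred_bbs, pred_cpm)
  report <- data.frame(phenotype = names(phen)[2],
                       method = c("BBS", "CPM"),
                       r = c(cmp$r_a, cmp$r_b),
                       p_diff = cmp$p_value, n = cmp$n)
  utils::write.csv(report, file.path(out, "prediction_report.csv"),
                   row.names = FALSE)
  stages$prediction <- c("cv_plateau.tsv", "prediction_report.csv")

  message("[network] SBM structure profile")
  nw <- cfg$network
  prof <- component_structure_profile(bas, scfg$community_assignment,
                                      n_perm = nw$n_perm, seed = seed + 40L,
                                      k = nw$n_components, alpha = nw$alpha)
  utils::write.table(prof, file.path(out, "sbm_profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stages$network <- "sbm_profile.tsv"

  message("[reliability] ICC on a fresh retest cohort")
  rl <- cfg$reliability
  retest_cfg <- scfg
  retest_cfg$n_subjects <- max(20L, cfg$split$n_test)
  retest_cfg$with_time_series <- FALSE
  retest_cfg$seed <- seed + 50L
  retest_sim <- simulate_subjects(retest_cfg)
  retest_sim$subject_ids <- paste0("rt_", retest_sim$subject_ids)
  rt <- simulate_retest(retest_sim, mode = "z_noise",
                        session_noise_sd = rl$session_noise_sd,
                        seed = seed + 51L)
  rep_icc <- icc_report(bas, rt, k = rl$k, n_perm = rl$n_perm,
                        seed = seed + 52L)
  jsonlite::write_json(
    list(mean_edge_icc = rep_icc$mean_edge_icc,
         mean_component_icc = rep_icc$mean_component_icc,
         null_mean = rep_icc$null$mean, null_ci = rep_icc$null$ci),
    file.path(out, "reliability.json"), auto_unbox = TRUE, digits = NA)
  stages$reliability <- "reliability.json"

  files <- unlist(stages, use.names = FALSE)
  manifest <- list(
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("connbasis")),
    stages = names(stages),
    checksums = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
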