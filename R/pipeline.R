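#' Load a pipeline run configuration
#'
#' A flat YAML key-value file; every omitted key falls back to the default
#' documented here, which is also the package-wide default of the
#' corresponding function.
#'
#' Keys (defaults in parentheses): `aptamer_fasta`, `protein_fasta`,
#' `pair_table`, `pssm_dir`, `disorder_dir`, `out_dir` (`"."`);
#' `omega` (0.5), `lambda2`/`lambda3` (corpus `L_min - K`), `n_dct` (52),
#' `max_lag` (51), `pssm_normalize` (`"sigmoid"`), `threshold` (0.5);
#' `n_neighbors` (10), `step` (1); `n_trees` (500), `folds` (10),
#' `seed` (1); simulation keys `n_pos`, `n_neg`, `effect_size` as in
#' [fixture_config()].
#'
#' @param path YAML path, or `NULL` for an all-defaults config.
#' @param ... Named overrides applied after the file.
#' @return A `run_config` list.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(out_dir = ".", omega = 0.5, lambda2 = NULL, lambda3 = NULL,
              n_dct = 52L, max_lag = 51L, pssm_normalize = "sigmoid",
              threshold = 0.5, n_neighbors = 10L, step = 1L,
              n_trees = 500L, folds = 10L, seed = 1L,
              n_pos = 50L, n_neg = 150L, effect_size = 1)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

write_manifest <- function(cfg, out_dir, command, outputs) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("aptensemble")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(command, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Simulate a synthetic corpus to disk
#'
#' @param cfg A [run_config()].
#' @return The fixture directory, invisibly.
#' @export
run_simulate <- function(cfg = run_config()) {
  ds <- generate_corpus(fixture_config(
    n_pos = cfg$n_pos, n_neg = cfg$n_neg,
    effect_size = cfg$effect_size, seed = cfg$seed))
  write_fixture(ds, cfg$out_dir)
  write_manifest(cfg, cfg$out_dir, "simulate",
                 file.path(cfg$out_dir, "pairs.tsv"))
  invisible(cfg$out_dir)
}

load_dataset <- function(cfg) {
  pairs <- read_pair_table(cfg$pair_table)
  apt <- read_fasta(cfg$aptamer_fasta, "nucleotide")
  prot <- read_fasta(cfg$protein_fasta, "protein")
  pair_dataset(pairs, apt, prot, pssm = cfg$pssm_dir,
               disorder = cfg$disorder_dir)
}

#' Extract the pair feature matrix
#'
#' Reads sequences, pairs, PSSMs and disorder tracks per the config,
#' builds the hybrid feature matrix and writes `features.tsv` (+ feature
#' dictionary) into `out_dir`, logging per-block dimensions.
#'
#' @param cfg A [run_config()] with input paths set.
#' @return The `feature_matrix`, invisibly.
#' @export
run_extract <- function(cfg) {
  ds <- load_dataset(cfg)
  fm <- build_feature_matrix(ds, lambda2 = cfg$lambda2,
                             lambda3 = cfg$lambda3, omega = cfg$omega,
                             n_dct = cfg$n_dct, max_lag = cfg$max_lag,
                             pssm_normalize = cfg$pssm_normalize,
                             threshold = cfg$threshold)
  tab <- table(fm$dictionary$block)
  message("feature blocks: ",
          paste(names(tab), tab, sep = "=", collapse = ", "),
          " (total ", ncol(fm$X), ")")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(cfg$out_dir, "features.tsv")
  write_feature_matrix(fm, out)
  write_manifest(cfg, cfg$out_dir, "extract", out)
  invisible(fm)
}

#' Rank features and run incremental feature selection
#'
#' Writes `relief_ranking.tsv`, `ifs_curve.tsv` and `optimal_features.txt`
#' into `out_dir`.
#'
#' @param cfg A [run_config()].
#' @param fm A `feature_matrix`; `NULL` reads `features.tsv` from
#'   `out_dir`.
#' @return The `ifs_result`, invisibly.
#' @export
run_select <- function(cfg, fm = NULL) {
  if (is.null(fm))
    fm <- read_feature_matrix(file.path(cfg$out_dir, "features.tsv"))
  ranked <- relief_rank(fm$X, fm$y, n_neighbors = cfg$n_neighbors,
                        seed = cfg$seed)
  ifs <- ifs_search(ranked, fm$X, fm$y, k = cfg$folds,
                    rf_params = rf_params(n_trees = cfg$n_trees),
                    step = cfg$step, seed = cfg$seed)
  write_ranked_features(ranked,
                        file.path(cfg$out_dir, "relief_ranking.tsv"))
  write_ifs_curve(ifs, file.path(cfg$out_dir, "ifs_curve.tsv"))
  writeLines(ifs$optimal_features,
             file.path(cfg$out_dir, "optimal_features.txt"))
  write_manifest(cfg, cfg$out_dir, "select",
                 file.path(cfg$out_dir,
                           c("relief_ranking.tsv", "ifs_curve.tsv",
                             "optimal_features.txt")))
  invisible(ifs)
}

#' Train the partition ensemble and persist it
#'
#' Trains on the optimal feature subset if `optimal_features.txt` exists in
#' `out_dir` (else all features) and saves the model directory
#' `model/` (metadata JSON + one RDS per base forest).
#'
#' @param cfg A [run_config()].
#' @param fm A `feature_matrix`; `NULL` reads `features.tsv`.
#' @return The `apt_ensemble`, invisibly.
#' @export
run_train <- function(cfg, fm = NULL) {
  if (is.null(fm))
    fm <- read_feature_matrix(file.path(cfg$out_dir, "features.tsv"))
  opt_path <- file.path(cfg$out_dir, "optimal_features.txt")
  X <- fm$X
  if (file.exists(opt_path))
    X <- X[, readLines(opt_path), drop = FALSE]
  part <- partition_negatives(fm$y, seed = cfg$seed)
  mod <- train_ensemble(part, X, fm$y,
                        params = rf_params(n_trees = cfg$n_trees),
                        seed = cfg$seed)
  mdir <- file.path(cfg$out_dir, "model")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(N = mod$N, n_trees = mod$params$n_trees,
                            seed = cfg$seed,
                            feature_names = mod$feature_names),
                       file.path(mdir, "model.json"), auto_unbox = TRUE)
  for (i in seq_len(mod$N))
    saveRDS(mod$models[[i]], file.path(mdir, sprintf("base_%02d.rds", i)))
  write_manifest(cfg, cfg$out_dir, "train",
                 file.path(mdir, "model.json"))
  invisible(mod)
}

#' Load a persisted ensemble model directory
#'
#' @param mdir Directory written by [run_train()].
#' @return An `apt_ensemble`.
#' @export
load_ensemble <- function(mdir) {
  meta <- jsonlite::read_json(file.path(mdir, "model.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(mdir, pattern = "^base_.*\\.rds$",
                           full.names = TRUE))
  structure(list(models = lapply(files, readRDS),
                 feature_names = meta$feature_names,
                 params = rf_params(n_trees = meta$n_trees),
                 N = meta$N),
            class = "apt_ensemble")
}

#' Predict pairs with a persisted model
#'
#' Writes `predictions.tsv` (pair, probability, label) into `out_dir`.
#'
#' @param cfg A [run_config()].
#' @param fm A `feature_matrix`; `NULL` reads `features.tsv`.
#' @return The prediction data.frame, invisibly.
#' @export
run_predict <- function(cfg, fm = NULL) {
  if (is.null(fm))
    fm <- read_feature_matrix(file.path(cfg$out_dir, "features.tsv"))
  mod <- load_ensemble(file.path(cfg$out_dir, "model"))
  pred <- predict(mod, fm$X[, mod$feature_names, drop = FALSE])
  out <- data.frame(pair = rownames(fm$X), pred,
                    stringsAsFactors = FALSE)
  write.table(out, file.path(cfg$out_dir, "predictions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(cfg, cfg$out_dir, "predict",
                 file.path(cfg$out_dir, "predictions.tsv"))
  invisible(out)
}

#' Evaluate by cross-validation or against held-out labels
#'
#' With `mode = "cv"`, runs stratified k-fold cross-validation of the
#' partition ensemble on the feature matrix; with `mode = "holdout"`,
#' scores existing `predictions.tsv` against the matrix labels. Writes
#' `metrics.tsv` (Sn, Sp, Acc, MCC, Youden) into `out_dir`.
#'
#' @param cfg A [run_config()].
#' @param fm A `feature_matrix`; `NULL` reads `features.tsv`.
#' @param mode `"cv"` or `"holdout"`.
#' @return Named metric vector, invisibly.
#' @export
run_evaluate <- function(cfg, fm = NULL, mode = c("cv", "holdout")) {
  mode <- match.arg(mode)
  if (is.null(fm))
    fm <- read_feature_matrix(file.path(cfg$out_dir, "features.tsv"))
  if (mode == "cv") {
    opt_path <- file.path(cfg$out_dir, "optimal_features.txt")
    X <- fm$X
    if (file.exists(opt_path))
      X <- X[, readLines(opt_path), drop = FALSE]
    res <- cross_validate(X, fm$y, k = cfg$folds,
                          rf_params = rf_params(n_trees = cfg$n_trees),
                          seed = cfg$seed)
    metrics <- res$mean
  } else {
    pred <- read.table(file.path(cfg$out_dir, "predictions.tsv"),
                       header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    metrics <- compute_metrics(confusion_counts(fm$y, pred$label))
  }
  out <- file.path(cfg$out_dir, "metrics.tsv")
  write.table(data.frame(metric = names(metrics),
                         value = round(unname(metrics), 3)),
              out, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, cfg$out_dir, "evaluate", out)
  invisible(metrics)
}
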