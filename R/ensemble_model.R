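#' Random-forest hyperparameters
#'
#' @param n_trees Trees per base forest (default 500).
#' @param mtry_rule Features tried per split: `"sqrt"` (default, floor of
#'   the square root of the feature count) or a positive integer.
#' @return An `rf_params` list.
#' @export
rf_params <- function(n_trees = 500L, mtry_rule = "sqrt") {
  structure(list(n_trees = as.integer(n_trees), mtry_rule = mtry_rule),
            class = "rf_params")
}

resolve_mtry <- function(rule, d) {
  if (identical(rule, "sqrt")) max(1L, floor(sqrt(d)))
  else as.integer(rule)
}

#' Partition the negative class for ensemble training
#'
#' Splits the majority (negative) samples into `N = floor(n_neg / n_pos)`
#' parts — the negative-to-positive ratio — after a seeded shuffle, with
#' part sizes differing by at most one; each part is joined with all
#' positive samples to form one balanced sub-training set. For the 1:3
#' benchmark ratio (580 positives, 1740 negatives) this yields N = 3
#' subsets of 1160 samples each.
#'
#' @param y Binary labels (1 = positive) or a [pair_dataset()].
#' @param seed Integer seed for the shuffle.
#' @return List of class `ensemble_partition`: `N`, `subsets` (each a list
#'   with integer index vectors `pos` and `neg`), `neg_parts`.
#' @export
partition_negatives <- function(y, seed = 1L) {
  if (inherits(y, "pair_dataset")) y <- y$pairs$label
  pos <- which(y == 1L)
  neg <- which(y != 1L)
  if (length(pos) < 1L) stop("no positive samples")
  if (length(neg) < length(pos))
    stop("fewer negatives (", length(neg), ") than positives (",
         length(pos), "); swap class roles or train a single model")
  N <- length(neg) %/% length(pos)
  set.seed(seed)
  shuffled <- sample(neg)
  part_id <- rep(seq_len(N), length.out = length(neg))  # sizes differ by <= 1
  neg_parts <- split(shuffled, part_id)
  subsets <- lapply(neg_parts, function(np) list(pos = pos,
                                                 neg = sort(np)))
  structure(list(N = N, subsets = subsets, neg_parts = neg_parts),
            class = "ensemble_partition")
}

#' Train the partition-ensemble random forest
#'
#' Fits one probability random forest per negative partition (each on all
#' positives plus one negative part), deterministically seeded per subset.
#'
#' @param partition An `ensemble_partition` from [partition_negatives()].
#' @param X Numeric feature matrix (all samples, by row index).
#' @param y Binary labels aligned with `X`.
#' @param params [rf_params()].
#' @param seed Base seed; subset i trains with `seed + i`.
#' @return List of class `apt_ensemble`: `models`, `feature_names`,
#'   `params`, `N`.
#' @export
train_ensemble <- function(partition, X, y, params = rf_params(),
                           seed = 1L) {
  stopifnot(inherits(partition, "ensemble_partition"), is.matrix(X))
  mtry <- resolve_mtry(params$mtry_rule, ncol(X))
  models <- lapply(seq_len(partition$N), function(i) {
    idx <- c(partition$subsets[[i]]$pos, partition$subsets[[i]]$neg)
    yy <- factor(y[idx], levels = c(0L, 1L))
    if (nlevels(droplevels(yy)) < 2L)
      stop("subset ", i, " is single-class; cannot train")
    ranger::ranger(x = X[idx, , drop = FALSE], y = yy,
                   num.trees = params$n_trees, mtry = mtry,
                   probability = TRUE, seed = seed + i,
                   num.threads = 1L)
  })
  structure(list(models = models, feature_names = colnames(X),
                 params = params, N = partition$N),
            class = "apt_ensemble")
}

#' Positive-class probability of a base model
#'
#' Generic so the averaging logic of [predict.apt_ensemble()] is
#' independent of the base learner.
#'
#' @param model A fitted base classifier.
#' @param X Feature matrix.
#' @return Numeric vector of positive-class probabilities.
#' @export
positive_prob <- function(model, X) UseMethod("positive_prob")

#' @export
positive_prob.ranger <- function(model, X) {
  pr <- predict(model, data = X, num.threads = 1L)$predictions
  as.numeric(pr[, "1"])
}

#' Predict interaction probabilities with the ensemble
#'
#' The ensemble probability is the unweighted mean of the base forests'
#' positive-class probabilities; a pair is called interacting when the
#' averaged probability is at least 0.5 (ties count as positive).
#'
#' @param object An `apt_ensemble`.
#' @param X Feature matrix whose columns match the training features.
#' @param ... Unused.
#' @return data.frame with `probability` and integer `label`.
#' @export
predict.apt_ensemble <- function(object, X, ...) {
  if (!identical(colnames(X), object$feature_names)) {
    missing_f <- setdiff(object$feature_names, colnames(X))
    extra_f <- setdiff(colnames(X), object$feature_names)
    if (length(missing_f) || length(extra_f))
      stop("feature mismatch; missing: ",
           paste(utils::head(missing_f, 5), collapse = ", "),
           "; extra: ", paste(utils::head(extra_f, 5), collapse = ", "))
    X <- X[, object$feature_names, drop = FALSE]
  }
  probs <- vapply(object$models, function(m) positive_prob(m, X),
                  numeric(nrow(X)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(X))
  p <- rowMeans(probs)
  data.frame(probability = p, label = as.integer(p >= 0.5))
}

#' Confusion counts from labels
#'
#' @param truth,pred Binary vectors (1 = positive).
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  c(TP = sum(truth == 1L & pred == 1L),
    FP = sum(truth == 0L & pred == 1L),
    TN = sum(truth == 0L & pred == 0L),
    FN = sum(truth == 1L & pred == 0L))
}

#' Classification metrics for imbalanced two-class problems
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, accuracy,
#' Matthews correlation coefficient, and Youden's index `J = Sn + Sp - 1`,
#' the imbalance-robust single-number summary used to compare predictors.
#' A metric whose denominator is zero is reported as 0 with a warning.
#'
#' @param counts Named vector with `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `Sn`, `Sp`, `Acc`, `MCC`, `Youden`.
#' @export
compute_metrics <- function(counts) {
  TP <- as.numeric(counts[["TP"]]); FP <- as.numeric(counts[["FP"]])
  TN <- as.numeric(counts[["TN"]]); FN <- as.numeric(counts[["FN"]])
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0",
              call. = FALSE)
      return(0)
    }
    num / den
  }
  sn <- safe(TP, TP + FN, "Sn")
  sp <- safe(TN, TN + FP, "Sp")
  acc <- safe(TP + TN, TP + FP + TN + FN, "Acc")
  mcc_den <- sqrt((TP + FN) * (TP + FP) * (TN + FP) * (TN + FN))
  mcc <- safe(TP * TN - FP * FN, mcc_den, "MCC")
  c(Sn = sn, Sp = sp, Acc = acc, MCC = mcc, Youden = sn + sp - 1)
}

make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop("class ", cls, " has ", length(idx), " samples; fewer than k = ",
           k, " folds — use a smaller k")
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Stratified cross-validation of the partition ensemble
#'
#' Stratified k-fold cross-validation: within each fold's training portion
#' the negative partition and the ensemble are rebuilt from scratch (no
#' leakage across folds), the held-out fold is scored, and metrics are
#' averaged over folds (set `pooled = TRUE` to compute them once from the
#' pooled confusion counts instead).
#'
#' @param X Feature matrix. @param y Binary labels.
#' @param k Folds (default 10).
#' @param rf_params [rf_params()].
#' @param seed Seed for folds, partitions, and forests.
#' @param folds Optional precomputed fold assignment (integer vector in
#'   `1..k`), e.g. to share folds across an IFS sweep.
#' @param pooled If `TRUE`, also report metrics of the pooled counts.
#' @return List: `mean` (named metric vector), `per_fold` (data.frame),
#'   `counts` (pooled confusion counts), and `pooled` metrics if requested.
#' @export
cross_validate <- function(X, y, k = 10L, rf_params = NULL, seed = 1L,
                           folds = NULL, pooled = FALSE) {
  if (is.null(rf_params)) rf_params <- aptensemble::rf_params()
  if (is.null(folds)) folds <- make_folds(y, k = k, seed = seed)
  per_fold <- vector("list", k)
  total <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L)
      stop("fold ", f, " lacks a class; use a smaller k")
    part <- partition_negatives(y[tr], seed = seed + f)
    mod <- train_ensemble(part, X[tr, , drop = FALSE], y[tr],
                          params = rf_params, seed = seed * 1000L + f)
    pred <- predict(mod, X[te, , drop = FALSE])
    cnt <- confusion_counts(y[te], pred$label)
    total <- total + cnt
    per_fold[[f]] <- suppressWarnings(compute_metrics(cnt))
  }
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  out <- list(mean = colMeans(per_fold), per_fold = per_fold,
              counts = total)
  if (pooled) out$pooled <- compute_metrics(total)
  out
}

#' Cross-validate a single (non-ensemble) random forest
#'
#' Same folds and metrics as [cross_validate()], but each fold trains one
#' forest on the full, imbalanced training portion. Provided as the
#' contrast that motivates the partition ensemble: on 1:3 data a single
#' forest favours the majority class (high Sp, low Sn).
#'
#' @inheritParams cross_validate
#' @return As [cross_validate()].
#' @export
cross_validate_single <- function(X, y, k = 10L, rf_params = NULL,
                                  seed = 1L, folds = NULL) {
  if (is.null(rf_params)) rf_params <- aptensemble::rf_params()
  if (is.null(folds)) folds <- make_folds(y, k = k, seed = seed)
  mtry <- resolve_mtry(rf_params$mtry_rule, ncol(X))
  per_fold <- vector("list", k)
  total <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    fit <- ranger::ranger(x = X[tr, , drop = FALSE],
                          y = factor(y[tr], levels = c(0L, 1L)),
                          num.trees = rf_params$n_trees, mtry = mtry,
                          probability = TRUE, seed = seed * 1000L + f,
                          num.threads = 1L)
    p <- positive_prob(fit, X[te, , drop = FALSE])
    cnt <- confusion_counts(y[te], as.integer(p >= 0.5))
    total <- total + cnt
    per_fold[[f]] <- suppressWarnings(compute_metrics(cnt))
  }
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  list(mean = colMeans(per_fold), per_fold = per_fold, counts = total)
}
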