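#' Rank features with Relief
#'
#' Relief scores each feature by how well it separates nearby samples of
#' different classes: for each sampled instance, its weight is decreased by
#' the (range-normalized) feature difference to the nearest hits (same
#' class) and increased by the difference to the nearest misses (other
#' class), averaged over instances. Defaults follow the common ReliefF
#' practice: 10 nearest neighbours per class, all instances sampled, no
#' distance weighting. With `n_neighbors = 1` the update rule reduces to
#' the original single-hit/single-miss formulation.
#'
#' Per-feature differences are normalized by the feature's range over the
#' data, so weights are comparable across features and invariant to affine
#' rescaling of any single feature; a zero-range (constant) feature gets
#' weight exactly 0. Neighbour search uses the Manhattan distance on the
#' range-normalized features.
#'
#' @param X Numeric matrix (samples x features), no missing values.
#' @param y Binary labels (two distinct values, each with >= 2 samples).
#' @param n_neighbors Nearest hits/misses aggregated per instance.
#' @param sample_size Number of instances sampled (default: all).
#' @param seed Integer seed for the instance sample order.
#' @return A data.frame of class `ranked_features` with columns `rank`,
#'   `name`, `weight`, ordered by descending weight (ties broken by
#'   original column order).
#' @export
relief_rank <- function(X, y, n_neighbors = 10L, sample_size = nrow(X),
                        seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  classes <- unique(y)
  if (length(classes) != 2L)
    stop("relief_rank needs exactly two classes, got ", length(classes))
  if (min(table(y)) < 2L) stop("each class needs at least 2 samples")
  rng <- apply(X, 2, function(v) diff(range(v)))
  keep <- rng > 0
  Xn <- X
  Xn[, keep] <- sweep(X[, keep, drop = FALSE], 2,
                      apply(X[, keep, drop = FALSE], 2, min))
  Xn[, keep] <- sweep(Xn[, keep, drop = FALSE], 2, rng[keep], "/")
  Xn[, !keep] <- 0
  n <- nrow(X)
  set.seed(seed)
  m <- min(sample_size, n)
  picks <- if (m == n) seq_len(n) else sample.int(n, m)
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  w <- numeric(ncol(X))
  for (i in picks) {
    same <- which(y == y[i]); same <- same[same != i]
    diffc <- which(y != y[i])
    hits <- same[order(D[i, same])][seq_len(min(n_neighbors, length(same)))]
    miss <- diffc[order(D[i, diffc])][seq_len(min(n_neighbors,
                                                  length(diffc)))]
    hit_diff <- colMeans(abs(Xn[hits, , drop = FALSE] -
                             Xn[rep(i, length(hits)), , drop = FALSE]))
    miss_diff <- colMeans(abs(Xn[miss, , drop = FALSE] -
                              Xn[rep(i, length(miss)), , drop = FALSE]))
    w <- w - hit_diff / m + miss_diff / m
  }
  ord <- order(-w, seq_along(w))
  structure(data.frame(rank = seq_along(w), name = colnames(X)[ord],
                       weight = w[ord], stringsAsFactors = FALSE),
            class = c("ranked_features", "data.frame"))
}

#' Incremental feature selection over a Relief ranking
#'
#' Evaluates growing prefixes of the ranked feature list — the top `step`,
#' `2 * step`, ... features and always the full set — with the
#' partition-ensemble cross-validation of [cross_validate()], using one
#' fixed fold assignment shared by every prefix so curve differences
#' reflect the features, not fold noise. The optimal subset is the prefix
#' maximizing mean Youden's index (smallest prefix on ties).
#'
#' @param ranked A `ranked_features` data.frame from [relief_rank()].
#' @param X,y Feature matrix and labels (columns must cover
#'   `ranked$name`).
#' @param k Cross-validation folds.
#' @param rf_params Random-forest parameters ([rf_params()]).
#' @param step Prefix increment; 1 reproduces the one-by-one procedure,
#'   larger values give a coarser, cheaper sweep.
#' @param seed Seed for folds and ensemble training.
#' @return List of class `ifs_result`: `curve` (data.frame: n_features,
#'   Sn, Sp, Acc, MCC, Youden), `optimal_n`, `optimal_features`.
#' @export
ifs_search <- function(ranked, X, y, k = 10L, rf_params = NULL, step = 1L,
                       seed = 1L) {
  stopifnot(inherits(ranked, "ranked_features"))
  if (is.null(rf_params)) rf_params <- aptensemble::rf_params()
  nm <- ranked$name
  if (!all(nm %in% colnames(X)))
    stop("ranked features missing from X: ",
         paste(utils::head(setdiff(nm, colnames(X)), 5), collapse = ", "))
  sizes <- unique(c(seq(step, length(nm), by = step), length(nm)))
  folds <- make_folds(y, k = k, seed = seed)
  rows <- lapply(sizes, function(sz) {
    cv <- cross_validate(X[, nm[seq_len(sz)], drop = FALSE], y, k = k,
                         rf_params = rf_params, seed = seed, folds = folds)
    c(n_features = sz, cv$mean)
  })
  curve <- as.data.frame(do.call(rbind, rows))
  best <- which(curve$Youden == max(curve$Youden))[1]  # smallest n on ties
  structure(list(curve = curve,
                 optimal_n = as.integer(curve$n_features[best]),
                 optimal_features = nm[seq_len(curve$n_features[best])]),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat("IFS over", max(x$curve$n_features), "features:",
      nrow(x$curve), "prefixes evaluated; optimal n =", x$optimal_n,
      "with mean Youden", round(max(x$curve$Youden), 3), "\n")
  invisible(x)
}

#' Write a Relief ranking / IFS curve as TSV
#'
#' @param ranked A `ranked_features` data.frame.
#' @param path Output path.
#' @export
write_ranked_features <- function(ranked, path) {
  write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_features
#' @param ifs An `ifs_result`.
#' @export
write_ifs_curve <- function(ifs, path) {
  write.table(ifs$curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
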