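test_that("negative partitioning follows the floor rule with even splits", {
  y <- rep(c(1L, 0L), c(580L, 1740L))
  part <- partition_negatives(y, seed = 1)
  expect_equal(part$N, 3L)
  sizes <- vapply(part$subsets,
                  function(s) length(s$pos) + length(s$neg), integer(1))
  expect_equal(unname(sizes), rep(1160L, 3))

  # conservation: parts are disjoint and cover all negatives exactly
  all_neg <- sort(unname(unlist(part$neg_parts)))
  expect_equal(all_neg, which(y == 0L))

  expect_equal(partition_negatives(rep(c(1L, 0L), each = 5))$N, 1L)

  p72 <- partition_negatives(rep(c(1L, 0L), c(2L, 7L)), seed = 9)
  expect_equal(p72$N, 3L)
  expect_equal(sort(unname(lengths(p72$neg_parts)), decreasing = TRUE),
               c(3L, 2L, 2L))
  expect_error(partition_negatives(rep(c(1L, 0L), c(5L, 3L))), "swap")
})

test_that("training yields one base forest per partition, deterministically", {
  ds <- small_corpus(n_pos = 10, n_neg = 30, effect_size = 2, seed = 5)
  fm <- build_feature_matrix(ds, lambda2 = 6, lambda3 = 5)
  part <- partition_negatives(fm$y, seed = 1)
  expect_equal(part$N, 3L)
  m1 <- train_ensemble(part, fm$X, fm$y, rf_params(50), seed = 7)
  expect_length(m1$models, 3)
  m2 <- train_ensemble(part, fm$X, fm$y, rf_params(50), seed = 7)
  expect_equal(predict(m1, fm$X), predict(m2, fm$X))

  one <- partition_negatives(rep(c(1L, 0L), each = 20), seed = 1)
  expect_equal(one$N, 1L)
})

test_that("ensemble probability is the unweighted mean with a >= 0.5 call", {
  stub <- function(p) structure(list(p = p), class = "const_model")
  registerS3method("positive_prob", "const_model",
                   function(model, X) rep(model$p, nrow(X)),
                   envir = asNamespace("aptensemble"))
  ens <- structure(list(models = list(stub(0.2), stub(0.4), stub(0.6)),
                        feature_names = c("f1", "f2"), N = 3L),
                   class = "apt_ensemble")
  X <- matrix(0, 2, 2, dimnames = list(NULL, c("f1", "f2")))
  pred <- predict(ens, X)
  expect_equal(pred$probability, c(0.4, 0.4))
  expect_equal(pred$label, c(0L, 0L))

  ens$models <- list(stub(1), stub(1), stub(1))
  expect_equal(predict(ens, X)$label, c(1L, 1L))
  ens$models <- list(stub(0.5), stub(0.5), stub(0.5))
  expect_equal(predict(ens, X)$label, c(1L, 1L))  # tie counts as positive

  expect_error(predict(ens, matrix(0, 1, 1, dimnames = list(NULL, "f1"))),
               "mismatch")
})

test_that("metrics reproduce published-style confusion arithmetic", {
  m <- compute_metrics(c(TP = 107, FN = 38, TN = 310, FP = 125))
  expect_equal(round(unname(m), 3), c(0.738, 0.713, 0.719, 0.398, 0.451))
  perfect <- compute_metrics(c(TP = 10, FN = 0, TN = 30, FP = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1, 1))
  expect_equal(0.3 + 0.993 - 1, 0.293, tolerance = 1e-12)

  set.seed(67)
  for (i in 1:50) {
    cnt <- c(TP = sample(0:50, 1), FP = sample(0:50, 1),
             TN = sample(0:50, 1), FN = sample(0:50, 1))
    m <- suppressWarnings(compute_metrics(cnt))
    expect_equal(m[["Youden"]], m[["Sn"]] + m[["Sp"]] - 1)  # exact identity
    swapped <- suppressWarnings(compute_metrics(
      c(TP = cnt[["TN"]], FP = cnt[["FN"]], TN = cnt[["TP"]],
        FN = cnt[["FP"]])))
    expect_equal(swapped[["MCC"]], m[["MCC"]], tolerance = 1e-12)
  }
  # no positives evaluated: both Sn and MCC are undefined and report 0
  expect_warning(
    expect_warning(compute_metrics(c(TP = 0, FN = 0, TN = 5, FP = 5)),
                   "Sn undefined"),
    "MCC undefined")
})

test_that("cross-validation separates a strong corpus and not a shuffled one", {
  ds <- small_corpus(n_pos = 24, n_neg = 72, effect_size = 12, seed = 11)
  fm <- build_feature_matrix(ds, lambda2 = 6, lambda3 = 5)
  cv <- cross_validate(fm$X, fm$y, k = 4, rf_params = rf_params(100),
                       seed = 1)
  expect_equal(nrow(cv$per_fold), 4)
  expect_gt(cv$mean[["Sn"]], 0.95)
  expect_gt(cv$mean[["Sp"]], 0.95)

  set.seed(71)
  J <- vapply(1:3, function(s) {
    y_shuf <- sample(fm$y)
    suppressWarnings(
      cross_validate(fm$X, y_shuf, k = 4, rf_params = rf_params(100),
                     seed = s)$mean[["Youden"]])
  }, numeric(1))
  expect_lt(abs(mean(J)), 0.1)
  expect_error(cross_validate(fm$X, fm$y, k = 30), "smaller k")
})
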