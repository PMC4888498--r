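scales <- load_hydropathy_scales()

test_that("hydropathy scales are standardized over the 20 residues", {
  for (sc in scales) {
    expect_length(sc, 20)
    expect_equal(mean(sc), 0, tolerance = 1e-12)
    expect_equal(mean(sc^2), 1, tolerance = 1e-12)
  }
})

test_that("DCT is orthonormal: constant signal, Parseval, oracle, linearity", {
  const_scale <- setNames(rep(1, 20),
                          strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  p <- random_aa(52)
  g <- dct_features(p, const_scale * 3, n_components = 52)
  expect_equal(g[1], 3 * sqrt(52))
  expect_equal(g[-1], rep(0, 51), tolerance = 1e-12)

  set.seed(23)
  p60 <- random_aa(60)
  H <- scales[[1]][strsplit(p60, "")[[1]]]
  full <- dct_features(p60, scales[[1]], n_components = 60)
  expect_equal(sum(full^2), sum(H^2), tolerance = 1e-10)  # Parseval
  expect_equal(dct_features(p60, scales[[1]], 52), oracle_dct(H, 52),
               tolerance = 1e-10)

  for (i in 1:100) {
    prot <- random_aa(sample(52:90, 1))
    Hp <- scales[[2]][strsplit(prot, "")[[1]]]
    expect_equal(dct_features(prot, scales[[2]], 52),
                 oracle_dct(unname(Hp), 52), tolerance = 1e-10)
  }
  alpha <- runif(1, 0.5, 3)
  expect_equal(dct_features(p60, scales[[1]] * alpha, 52),
               alpha * dct_features(p60, scales[[1]], 52),
               tolerance = 1e-10)
  expect_error(dct_features(random_aa(40), scales[[1]], 52), "pad")
  expect_length(dct_features(random_aa(40), scales[[1]], 52, pad = TRUE), 52)
})

test_that("bi-gram PSSM features follow the transition-product definition", {
  zero <- matrix(0, 5, 20)
  expect_equal(unname(bigram_pssm_features(zero, normalize = "none")),
               rep(0, 400))
  unit <- matrix(0, 2, 20)
  unit[1, 3] <- 1; unit[2, 7] <- 1
  b <- bigram_pssm_features(unit, normalize = "none")
  expect_length(b, 400)
  expect_equal(unname(b[(3 - 1) * 20 + 7]), 1)  # B[3,7] in row-major order
  expect_equal(sum(b), 1)

  set.seed(29)
  for (i in 1:100) {
    P <- matrix(rnorm(sample(2:10, 1) * 20), ncol = 20)
    expect_equal(unname(bigram_pssm_features(P, normalize = "none")),
                 oracle_bigram(P), tolerance = 1e-10)
  }
  # sigmoid mode equals the definition applied to the squashed matrix
  P <- matrix(sample(-10:10, 8 * 20, TRUE), 8, 20)
  expect_equal(unname(bigram_pssm_features(P, normalize = "sigmoid")),
               oracle_bigram(1 / (1 + exp(-P))), tolerance = 1e-10)
  expect_error(bigram_pssm_features(matrix(0, 1, 20)), "L >= 2")
})

test_that("bi-gram sum identity holds for non-negative matrices", {
  set.seed(31)
  for (i in 1:20) {
    P <- matrix(runif(sample(3:12, 1) * 20), ncol = 20)
    b <- bigram_pssm_features(P, normalize = "none")
    rs <- rowSums(P)
    L <- nrow(P)
    expect_equal(sum(b), sum(rs[1:(L - 1)] * rs[2:L]), tolerance = 1e-10)
  }
})

test_that("disorder autocovariance matches direct summation", {
  expect_equal(disorder_autocovariance(rep(0.7, 60), max_lag = 51),
               rep(0, 51))
  set.seed(37)
  for (i in 1:100) {
    L <- sample(52:90, 1)
    d <- runif(L)
    expect_equal(disorder_autocovariance(d, 51), oracle_ac(d, 51),
                 tolerance = 1e-12)
    # shift invariance (bounded so scores stay interpretable)
    expect_equal(disorder_autocovariance(d / 2 + 0.25, 51),
                 disorder_autocovariance(d / 2, 51), tolerance = 1e-12)
  }
  expect_error(disorder_autocovariance(runif(51), 51), "exceed")
})

test_that("segment features implement the run-length definition", {
  s <- disorder_segment_features(rep(0.9, 10))
  expect_equal(unname(s[c("dis_mean", "dis_sd")]), c(0.9, 0))
  expect_equal(unname(s[c("n_dis_seg", "n_ord_seg")]), c(1, 0))
  expect_equal(unname(s[c("dis_seg_min", "dis_seg_max")]), c(10, 10))
  expect_equal(unname(s[c("ord_seg_min", "ord_seg_max")]), c(0, 0))

  s2 <- disorder_segment_features(c(0.9, 0.9, 0.1, 0.9))
  expect_equal(unname(s2["n_dis_seg"]), 2)
  expect_equal(unname(s2["n_ord_seg"]), 1)
  expect_equal(unname(s2[c("dis_seg_min", "dis_seg_max")]), c(1, 2))

  set.seed(41)
  for (i in 1:50) {
    d <- runif(sample(5:80, 1))
    s <- disorder_segment_features(d)
    expect_gte(s[["n_dis_seg"]] + s[["n_ord_seg"]], 1)
    # segment lengths tile the track
    r <- rle(d >= 0.5)
    expect_equal(sum(r$lengths), length(d))
  }
})

test_that("protein encoding concatenates 104 + 400 + 59 = 563 features", {
  set.seed(43)
  L <- 60
  prot <- random_aa(L)
  pssm <- matrix(sample(-10:10, L * 20, TRUE), L, 20)
  track <- runif(L)
  v <- encode_protein(prot, pssm, track)
  expect_length(v, 563)
  expect_equal(sum(grepl("^dct_", names(v))), 104)
  expect_equal(sum(grepl("^bg_", names(v))), 400)
  expect_equal(sum(grepl("^dis_|^n_|^ord_", names(v))), 59)

  v0 <- encode_protein(prot, matrix(0, L, 20), track,
                       pssm_normalize = "none")
  expect_equal(unname(v0[grepl("^bg_", names(v0))]), rep(0, 400))
  expect_equal(v0[grepl("^dct_", names(v0))], v[grepl("^dct_", names(v))])
  expect_error(encode_protein(prot, pssm[1:10, ], track), "rows")
  expect_error(encode_protein(prot, pssm, track[1:10]), "scores")
})
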