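# Independent brute-force oracles, written as literal double/triple loops
# over the defining formulas. They share no code with the package paths
# they check.

oracle_theta <- function(seq, table, lambda) {
  K <- table$K
  L <- nchar(seq)
  n_t <- L - K + 1
  H <- matrix(NA_real_, n_t, length(table$property_names))
  for (i in seq_len(n_t))
    H[i, ] <- table$values[substr(seq, i, i + K - 1), ]
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    acc <- 0
    for (i in seq_len(n_t - j)) {
      big <- 0
      for (p in seq_len(ncol(H))) big <- big + (H[i, p] - H[i + j, p])^2
      acc <- acc + big / ncol(H)
    }
    theta[j] <- acc / (n_t - j)
  }
  theta
}

oracle_pseknc <- function(seq, table, K, lambda, omega) {
  L <- nchar(seq)
  lev <- aptensemble::ktuples(K)
  f <- setNames(numeric(length(lev)), lev)
  for (i in seq_len(L - K + 1)) {
    t <- substr(seq, i, i + K - 1)
    f[t] <- f[t] + 1
  }
  f <- f / (L - K + 1)
  th <- oracle_theta(seq, table, lambda)
  unname(c(f, omega * th) / (sum(f) + omega * sum(th)))
}

oracle_dct <- function(H, n_components) {
  L <- length(H)
  G <- numeric(n_components)
  for (k in 0:(n_components - 1)) {
    a <- if (k == 0) sqrt(1 / L) else sqrt(2 / L)
    s <- 0
    for (n in 0:(L - 1)) s <- s + H[n + 1] * cos((2 * n + 1) * k * pi / (2 * L))
    G[k + 1] <- a * s
  }
  G
}

oracle_bigram <- function(P) {
  L <- nrow(P)
  B <- matrix(0, 20, 20)
  for (m in 1:20)
    for (n in 1:20)
      for (i in 1:(L - 1))
        B[m, n] <- B[m, n] + P[i, m] * P[i + 1, n]
  as.numeric(t(B))
}

oracle_ac <- function(d, max_lag) {
  L <- length(d)
  dbar <- mean(d)
  ac <- numeric(max_lag)
  for (lag in seq_len(max_lag)) {
    s <- 0
    for (i in seq_len(L - lag)) s <- s + (d[i] - dbar) * (d[i + lag] - dbar)
    ac[lag] <- s / (L - lag)
  }
  ac
}

# Single-nearest-hit/miss Relief over all instances, range-normalized diffs.
oracle_relief1 <- function(X, y) {
  n <- nrow(X); d <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  Xn <- X
  for (p in seq_len(d)) {
    if (rng[p] > 0) Xn[, p] <- (X[, p] - min(X[, p])) / rng[p]
    else Xn[, p] <- 0
  }
  w <- numeric(d)
  for (i in seq_len(n)) {
    dist_i <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j == i) next
      dist_i[j] <- sum(abs(Xn[i, ] - Xn[j, ]))
    }
    same <- which(y == y[i] & seq_len(n) != i)
    diffc <- which(y != y[i])
    hit <- same[which.min(dist_i[same])]
    miss <- diffc[which.min(dist_i[diffc])]
    for (p in seq_len(d))
      w[p] <- w[p] - abs(Xn[i, p] - Xn[hit, p]) / n +
        abs(Xn[i, p] - Xn[miss, p]) / n
  }
  w
}

random_nt <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE), collapse = "")
random_aa <- function(L) paste(sample(strsplit(
  "ARNDCQEGHILKMFPSTWYV", "")[[1]], L, replace = TRUE), collapse = "")

small_corpus <- function(n_pos = 15, n_neg = 45, effect_size = 1,
                         seed = 1) {
  generate_corpus(fixture_config(n_pos = n_pos, n_neg = n_neg,
                                 effect_size = effect_size, seed = seed))
}
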