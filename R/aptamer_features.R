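NT4 <- c("A", "C", "G", "T")

#' Enumerate K-tuples in lexicographic order
#'
#' Tuples are ordered lexicographically over A < C < G < T so feature names
#' are stable across runs.
#'
#' @param K Tuple size (2 or 3).
#' @return Character vector of length 4^K.
#' @export
ktuples <- function(K) {
  grid <- do.call(expand.grid,
                  c(rev(replicate(K, NT4, simplify = FALSE)),
                    list(stringsAsFactors = FALSE)))
  sort(apply(grid[, rev(seq_len(K)), drop = FALSE], 1, paste, collapse = ""))
}

#' Load a K-tuple physicochemical property table
#'
#' Reads a TSV (columns: `tuple`, then one column per property) and
#' standardizes each property to mean 0 and population standard deviation 1
#' across the 4^K tuples, the normalization under which squared property
#' differences between tuples are scale-free.
#'
#' The tables shipped with the package
#' (`dinucleotide_properties_synthetic.tsv`, 6 helical step parameters:
#' twist, tilt, roll, shift, slide, rise;
#' `trinucleotide_properties_synthetic.tsv`, 12 properties formed by the
#' step parameters of the two constituent dinucleotide steps) are synthetic
#' stand-ins with realistic B-DNA ranges and complementary symmetry; supply
#' your own TSV to use a specific published compilation. Because every
#' property is standardized at load, downstream features are invariant to
#' affine rescaling of the raw table values.
#'
#' @param path TSV path; `NULL` loads the shipped table for `K`.
#' @param K Tuple size (2 or 3), used only when `path` is `NULL`.
#' @return A `ktuple_table`: list with `K`, `property_names` and `values`
#'   (4^K x N standardized matrix, rownames = tuples).
#' @export
load_property_table <- function(path = NULL, K = NULL) {
  if (is.null(path)) {
    stopifnot(K %in% c(2L, 3L))
    fname <- if (K == 2L) "dinucleotide_properties_synthetic.tsv"
             else "trinucleotide_properties_synthetic.tsv"
    path <- system.file("extdata", fname, package = "aptensemble",
                        mustWork = TRUE)
  }
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "tuple") stop("property table must start with 'tuple'")
  K <- nchar(df$tuple[1])
  raw <- as.matrix(df[, -1, drop = FALSE])
  rownames(raw) <- toupper(chartr("U", "T", df$tuple))
  want <- ktuples(K)
  missing_t <- setdiff(want, rownames(raw))
  if (length(missing_t))
    stop("property table missing tuple(s): ",
         paste(utils::head(missing_t, 5), collapse = ", "))
  standardize_properties(raw[want, , drop = FALSE], K = K)
}

#' Standardize a raw property matrix
#'
#' Per property (column): subtract the mean and divide by the population
#' standard deviation over the 4^K tuples. Idempotent on already-standardized
#' values; a zero-variance (uninformative) property is an error.
#'
#' @param raw 4^K x N numeric matrix, rownames = tuples.
#' @param K Tuple size.
#' @return A `ktuple_table` object.
#' @export
standardize_properties <- function(raw, K = nchar(rownames(raw)[1])) {
  mu <- colMeans(raw)
  sdev <- sqrt(colMeans(sweep(raw, 2, mu)^2))
  if (any(sdev <= 0))
    stop("zero-variance property: ",
         paste(colnames(raw)[sdev <= 0], collapse = ", "))
  vals <- sweep(sweep(raw, 2, mu), 2, sdev, "/")
  structure(list(K = as.integer(K), property_names = colnames(raw),
                 values = vals),
            class = "ktuple_table")
}

#' Normalized K-tuple occurrence frequencies
#'
#' Counts of the L - K + 1 overlapping K-tuples divided by L - K + 1, in
#' fixed lexicographic tuple order; entries sum to 1.
#'
#' @param seq A residue string over A/C/G/T (U accepted, mapped to T).
#' @param K Tuple size.
#' @return Named numeric vector of length 4^K.
#' @export
ktuple_frequencies <- function(seq, K) {
  s <- chartr("U", "T", toupper(seq))
  L <- nchar(s)
  if (L < K) stop("sequence of length ", L, " is shorter than K = ", K)
  tuples <- substring(s, 1:(L - K + 1), K:L)
  lev <- ktuples(K)
  tab <- table(factor(tuples, levels = lev))
  setNames(as.numeric(tab) / (L - K + 1), lev)
}

tuple_property_rows <- function(seq, table) {
  K <- table$K
  s <- chartr("U", "T", toupper(seq))
  L <- nchar(s)
  tuples <- substring(s, 1:(L - K + 1), K:L)
  table$values[tuples, , drop = FALSE]
}

#' Sequence-order correlation factors
#'
#' The j-th factor is the average, over all tuple positions i, of the
#' correlation function between the tuples at i and i + j: the mean squared
#' difference of their N standardized property values. Identical tuples
#' contribute 0, so every factor is non-negative and a homopolymer yields an
#' all-zero vector.
#'
#' @param seq Residue string.
#' @param table A `ktuple_table`.
#' @param lambda Highest correlation tier; must satisfy
#'   `lambda <= nchar(seq) - K`.
#' @return Numeric vector `theta` of length `lambda`.
#' @export
correlation_factors <- function(seq, table, lambda) {
  K <- table$K
  L <- nchar(seq)
  if (lambda < 1L) stop("lambda must be >= 1")
  if (lambda > L - K)
    stop("lambda = ", lambda, " exceeds L - K = ", L - K,
         " for sequence '", substr(seq, 1, 12), "...' (L = ", L, ")")
  H <- tuple_property_rows(seq, table)   # (L-K+1) x N standardized values
  n_t <- nrow(H)
  vapply(seq_len(lambda), function(j) {
    d <- H[1:(n_t - j), , drop = FALSE] - H[(1 + j):n_t, , drop = FALSE]
    mean(rowMeans(d^2))
  }, numeric(1))
}

#' Pseudo K-tuple nucleotide composition configuration
#'
#' @param K Tuple size (2 or 3).
#' @param lambda Number of correlation tiers; the canonical choice is
#'   `L_min - K` where `L_min` is the minimum aptamer length of the training
#'   corpus ([corpus_min_length()]).
#' @param omega Weight factor balancing composition against sequence-order
#'   correlation; default 0.5, the conventional PseKNC setting.
#' @return A `pseknc_config` list.
#' @export
pseknc_config <- function(K, lambda, omega = 0.5) {
  stopifnot(K %in% c(2L, 3L), lambda >= 1, omega > 0)
  structure(list(K = as.integer(K), lambda = as.integer(lambda),
                 omega = omega), class = "pseknc_config")
}

#' Pseudo K-tuple nucleotide composition vector
#'
#' The (4^K + lambda)-dimensional encoding: the first 4^K entries are the
#' tuple frequencies and the last lambda the omega-weighted correlation
#' factors, jointly normalized so the vector is non-negative and sums to 1.
#'
#' @param seq Residue string.
#' @param table A `ktuple_table` with `table$K == config$K`.
#' @param config A [pseknc_config()].
#' @return Named numeric vector of length `4^K + lambda`
#'   (`pse<K>_<tuple>` then `pse<K>_theta<j>`).
#' @export
pseknc_vector <- function(seq, table, config) {
  stopifnot(inherits(config, "pseknc_config"), table$K == config$K)
  f <- ktuple_frequencies(seq, config$K)
  th <- correlation_factors(seq, table, config$lambda)
  denom <- sum(f) + config$omega * sum(th)
  v <- c(f, config$omega * th) / denom
  names(v) <- c(paste0("pse", config$K, "_", names(f)),
                paste0("pse", config$K, "_theta", seq_len(config$lambda)))
  v
}

#' Encode an aptamer with pseudo di- and tri-nucleotide composition
#'
#' Concatenates the K = 2 and K = 3 PseKNC vectors. With the benchmark-style
#' configuration (minimum aptamer length 8, so lambda2 = 6 and lambda3 = 5)
#' the block has (16 + 6) + (64 + 5) = 91 features.
#'
#' @param seq Residue string.
#' @param tables List with elements `k2` and `k3` (`ktuple_table`s); `NULL`
#'   loads the shipped tables.
#' @param lambda2,lambda3 Correlation tiers for K = 2 and K = 3.
#' @param omega Weight factor shared by both components.
#' @return Named numeric vector of length `(16 + lambda2) + (64 + lambda3)`.
#' @export
encode_aptamer <- function(seq, tables = NULL, lambda2 = 6L, lambda3 = 5L,
                           omega = 0.5) {
  if (is.null(tables)) tables <- default_ktuple_tables()
  c(pseknc_vector(seq, tables$k2, pseknc_config(2L, lambda2, omega)),
    pseknc_vector(seq, tables$k3, pseknc_config(3L, lambda3, omega)))
}

table_cache <- new.env(parent = emptyenv())

default_ktuple_tables <- function() {
  if (is.null(table_cache$tables))
    table_cache$tables <- list(k2 = load_property_table(K = 2L),
                               k3 = load_property_table(K = 3L))
  table_cache$tables
}
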