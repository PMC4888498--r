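#' Load hydropathy scales
#'
#' Reads per-residue hydropathy values (TSV: `residue`, then one column per
#' scale) and standardizes each scale to mean 0 / population sd 1 over the
#' 20 amino acids. The shipped defaults are Kyte-Doolittle hydrophobicity
#' and Hopp-Woods hydrophilicity, the most common pairing for
#' periodicity-style sequence features; both are user-replaceable.
#'
#' @param path TSV path; `NULL` loads the shipped scales.
#' @return Named list of named numeric vectors (one per scale), each with
#'   entries for the 20 standard amino acids.
#' @export
load_hydropathy_scales <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hydropathy_scales.tsv",
                        package = "aptensemble", mustWork = TRUE)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "residue") stop("scale table must start with 'residue'")
  missing_aa <- setdiff(AA_ALPHABET, df$residue)
  if (length(missing_aa))
    stop("scale table missing residue(s): ",
         paste(missing_aa, collapse = ", "))
  lapply(setNames(names(df)[-1], names(df)[-1]), function(col) {
    v <- setNames(df[[col]], df$residue)[AA_ALPHABET]
    mu <- mean(v)
    sdev <- sqrt(mean((v - mu)^2))
    if (sdev <= 0) stop("constant hydropathy scale '", col, "'")
    (v - mu) / sdev
  })
}

hydropathy_signal <- function(protein, scale) {
  ch <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  v <- scale[ch]
  v[is.na(v)] <- 0  # permissive ambiguity codes contribute zero
  unname(v)
}

#' Low-frequency discrete cosine transform features
#'
#' Applies the orthonormal type-II DCT,
#' `G(k) = a(k) * sum_n H(p_n) cos((2n+1) k pi / (2L))` with
#' `a(0) = sqrt(1/L)`, `a(k) = sqrt(2/L)` otherwise, to the per-residue
#' hydropathy signal and keeps the first `n_components` coefficients. The
#' low-frequency coefficients compress the global shape and periodicity of
#' the signal into a fixed-length descriptor.
#'
#' @param protein Residue string.
#' @param scale Named numeric vector (residue -> value), typically one
#'   element of [load_hydropathy_scales()].
#' @param n_components Number of leading coefficients to keep; default 52,
#'   the minimum protein length of the benchmark corpus.
#' @param pad If `TRUE`, proteins shorter than `n_components` are
#'   zero-padded to `n_components` instead of raising an error (exploratory
#'   use only).
#' @return Numeric vector of length `n_components`.
#' @export
dct_features <- function(protein, scale, n_components = 52L, pad = FALSE) {
  H <- hydropathy_signal(protein, scale)
  L <- length(H)
  if (L < n_components) {
    if (!pad)
      stop("protein length ", L, " < n_components = ", n_components,
           "; set pad = TRUE to zero-pad")
    H <- c(H, rep(0, n_components - L))
    L <- length(H)
  }
  k <- 0:(n_components - 1)
  n <- 0:(L - 1)
  a <- ifelse(k == 0, sqrt(1 / L), sqrt(2 / L))
  # cos basis: n_components x L
  basis <- cos(outer(k, 2 * n + 1) * pi / (2 * L))
  as.numeric(a * (basis %*% H))
}

#' Bi-gram PSSM transition features
#'
#' For an L x 20 PSSM P, computes the 400 values
#' `B[m, n] = sum_{i=1}^{L-1} P[i, m] * P[i+1, n]`, the evolutionary
#' analogue of amino-acid bi-gram counts, flattened row-major
#' (`B[1,1] ... B[1,20], B[2,1] ...`). Raw PSI-BLAST log-odds are by default
#' squashed element-wise through the logistic function `1/(1+exp(-x))` so
#' products are scale-stable; `normalize = "none"` uses the raw entries.
#'
#' @param pssm L x 20 numeric matrix (L >= 2).
#' @param normalize `"sigmoid"` (default) or `"none"`.
#' @return Named numeric vector of length 400 (`bg_<m>_<n>` with m, n the
#'   amino acids in PSI-BLAST column order).
#' @export
bigram_pssm_features <- function(pssm, normalize = c("sigmoid", "none")) {
  normalize <- match.arg(normalize)
  if (!is.matrix(pssm) || ncol(pssm) != 20L)
    stop("PSSM must be an L x 20 matrix")
  L <- nrow(pssm)
  if (L < 2L) stop("bi-gram features need L >= 2 (got L = ", L, ")")
  P <- if (normalize == "sigmoid") 1 / (1 + exp(-pssm)) else pssm
  B <- crossprod(P[1:(L - 1), , drop = FALSE], P[2:L, , drop = FALSE])
  aa <- PSSM_COLUMNS
  setNames(as.numeric(t(B)),
           paste0("bg_", rep(aa, each = 20L), "_", rep(aa, 20L)))
}

#' Autocovariance of a disorder-score track
#'
#' `AC[lag] = (1/(L - lag)) * sum_i (d_i - dbar)(d_{i+lag} - dbar)` with the
#' global track mean `dbar`, for lag = 1 ... `max_lag`. Lags up to
#' `L_min - 1 = 51` (benchmark minimum protein length 52) give a
#' fixed-length order-aware summary of tracks of varying length.
#'
#' @param track Numeric vector of per-residue disorder scores.
#' @param max_lag Largest lag; requires `length(track) > max_lag`.
#' @return Numeric vector of length `max_lag`.
#' @export
disorder_autocovariance <- function(track, max_lag = 51L) {
  L <- length(track)
  if (L <= max_lag)
    stop("track length ", L, " must exceed max_lag = ", max_lag)
  dbar <- mean(track)
  cent <- track - dbar
  vapply(seq_len(max_lag), function(lag) {
    sum(cent[1:(L - lag)] * cent[(1 + lag):L]) / (L - lag)
  }, numeric(1))
}

#' Global and segment summaries of a disorder track
#'
#' A residue is disordered when its score is at least `threshold` (0.5,
#' the usual binary convention of disorder predictors). A segment is a
#' maximal run of residues on the same side of the threshold. Returns 8
#' features: mean and population standard deviation of the scores, the
#' number of disordered and non-disordered segments, and the minimum and
#' maximum lengths of each segment class. An absent segment class reports
#' min = max = 0 (an explicit sentinel).
#'
#' @param track Numeric vector of per-residue disorder scores.
#' @param threshold Disorder threshold in \[0, 1\].
#' @return Named numeric vector of length 8.
#' @export
disorder_segment_features <- function(track, threshold = 0.5) {
  if (length(track) == 0L) stop("empty disorder track")
  disordered <- track >= threshold
  r <- rle(disordered)
  dis_len <- r$lengths[r$values]
  ord_len <- r$lengths[!r$values]
  seg_range <- function(x) if (length(x)) c(min(x), max(x)) else c(0, 0)
  c(dis_mean = mean(track),
    dis_sd = sqrt(mean((track - mean(track))^2)),
    n_dis_seg = length(dis_len),
    n_ord_seg = length(ord_len),
    dis_seg_min = seg_range(dis_len)[1],
    dis_seg_max = seg_range(dis_len)[2],
    ord_seg_min = seg_range(ord_len)[1],
    ord_seg_max = seg_range(ord_len)[2])
}

#' Encode a target protein with hybrid features
#'
#' Concatenates the three protein descriptors in fixed order:
#' `n_dct` DCT coefficients per hydropathy scale (2 x 52 = 104 by default),
#' 400 bi-gram PSSM features, and `max_lag + 8` disorder features
#' (51 + 8 = 59 by default) — 563 features in total.
#'
#' @param protein Residue string.
#' @param pssm L x 20 matrix (a zero matrix is the accepted no-homolog
#'   fallback and yields an all-zero bi-gram sub-block under
#'   `normalize = "none"`).
#' @param track Disorder-score vector of length L.
#' @param scales List of standardized hydropathy scales; `NULL` loads the
#'   shipped Kyte-Doolittle / Hopp-Woods pair.
#' @param n_dct DCT coefficients per scale (default 52).
#' @param max_lag Autocovariance lags (default 51).
#' @param pssm_normalize Passed to [bigram_pssm_features()].
#' @param threshold Passed to [disorder_segment_features()].
#' @param pad Passed to [dct_features()].
#' @return Named numeric vector of length
#'   `length(scales) * n_dct + 400 + max_lag + 8`.
#' @export
encode_protein <- function(protein, pssm, track, scales = NULL,
                           n_dct = 52L, max_lag = 51L,
                           pssm_normalize = "sigmoid", threshold = 0.5,
                           pad = FALSE) {
  if (is.null(scales)) scales <- default_hydropathy_scales()
  L <- nchar(protein)
  if (nrow(pssm) != L)
    stop("PSSM has ", nrow(pssm), " rows but protein length is ", L)
  if (length(track) != L)
    stop("disorder track has ", length(track),
         " scores but protein length is ", L)
  dct <- unlist(lapply(seq_along(scales), function(i) {
    v <- dct_features(protein, scales[[i]], n_components = n_dct, pad = pad)
    setNames(v, paste0("dct_", names(scales)[i], "_", seq_len(n_dct) - 1L))
  }))
  bg <- bigram_pssm_features(pssm, normalize = pssm_normalize)
  ac <- setNames(disorder_autocovariance(track, max_lag = max_lag),
                 paste0("dis_ac", seq_len(max_lag)))
  seg <- disorder_segment_features(track, threshold = threshold)
  c(dct, bg, ac, seg)
}

scale_cache <- new.env(parent = emptyenv())

default_hydropathy_scales <- function() {
  if (is.null(scale_cache$scales))
    scale_cache$scales <- load_hydropathy_scales()
  scale_cache$scales
}
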