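#' Build the pair feature matrix
#'
#' Encodes every aptamer-protein pair of a dataset as the concatenation of
#' the aptamer block ([encode_aptamer()], `(16 + lambda2) + (64 + lambda3)`
#' features) and the protein block ([encode_protein()], 563 features by
#' default). Under the benchmark length configuration (aptamer minimum
#' length 8 so lambda2 = 6, lambda3 = 5; protein minimum length 52) the
#' matrix has 91 + 563 = 654 columns.
#'
#' Per-aptamer and per-protein encodings are computed once and reused across
#' pairs.
#'
#' @param dataset A [pair_dataset()] with PSSM and disorder stores.
#' @param lambda2,lambda3,omega Aptamer encoder parameters; `lambda2`/
#'   `lambda3` default to `L_min - K` of the dataset's aptamer corpus.
#' @param tables,scales Property tables / hydropathy scales (`NULL` =
#'   shipped defaults).
#' @param n_dct,max_lag,pssm_normalize,threshold Protein encoder parameters.
#' @return List of class `feature_matrix`: `X` (pairs x features numeric
#'   matrix), `y` (integer labels, 1 = interacting), `dictionary`
#'   (data.frame: name, block, index).
#' @export
build_feature_matrix <- function(dataset, lambda2 = NULL, lambda3 = NULL,
                                 omega = 0.5, tables = NULL, scales = NULL,
                                 n_dct = 52L, max_lag = 51L,
                                 pssm_normalize = "sigmoid",
                                 threshold = 0.5) {
  stopifnot(inherits(dataset, "pair_dataset"))
  lmin <- corpus_min_length(dataset$aptamers)
  if (is.null(lambda2)) lambda2 <- lmin - 2L
  if (is.null(lambda3)) lambda3 <- lmin - 3L
  apt_ids <- unique(dataset$pairs$aptamer_id)
  apt_enc <- lapply(setNames(apt_ids, apt_ids), function(id)
    encode_aptamer(dataset$aptamers[[id]], tables = tables,
                   lambda2 = lambda2, lambda3 = lambda3, omega = omega))
  prot_ids <- unique(dataset$pairs$protein_id)
  prot_enc <- lapply(setNames(prot_ids, prot_ids), function(id)
    encode_protein(dataset$proteins[[id]], dataset$pssm[[id]],
                   dataset$disorder[[id]], scales = scales, n_dct = n_dct,
                   max_lag = max_lag, pssm_normalize = pssm_normalize,
                   threshold = threshold))
  X <- t(mapply(function(a, p) c(apt_enc[[a]], prot_enc[[p]]),
                dataset$pairs$aptamer_id, dataset$pairs$protein_id))
  rownames(X) <- paste(dataset$pairs$aptamer_id,
                       dataset$pairs$protein_id, sep = "|")
  n_apt <- length(apt_enc[[1]])
  blocks <- c(rep("pseknc", n_apt),
              rep("dct", length(default_or(scales)) * n_dct),
              rep("bigram_pssm", 400L),
              rep("disorder", max_lag + 8L))
  dict <- data.frame(name = colnames(X), block = blocks,
                     index = seq_len(ncol(X)), stringsAsFactors = FALSE)
  structure(list(X = X, y = dataset$pairs$label, dictionary = dict),
            class = "feature_matrix")
}

default_or <- function(scales) {
  if (is.null(scales)) default_hydropathy_scales() else scales
}

#' Write a feature matrix and its dictionary as TSV
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()].
#' @param path Output TSV for the matrix (`pair`, `label`, then features);
#'   the dictionary goes to `<path>.dict.tsv`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(pair = rownames(fm$X), label = fm$y, fm$X,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fm$dictionary, paste0(path, ".dict.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return A `feature_matrix` (dictionary re-read if present alongside).
#' @export
read_feature_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  X <- as.matrix(df[, setdiff(names(df), c("pair", "label")), drop = FALSE])
  rownames(X) <- df$pair
  dict_path <- paste0(path, ".dict.tsv")
  dict <- if (file.exists(dict_path))
    read.table(dict_path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE) else NULL
  structure(list(X = X, y = as.integer(df$label), dictionary = dict),
            class = "feature_matrix")
}
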