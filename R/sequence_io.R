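#' @importFrom stats predict rnorm runif sd setNames
#' @importFrom utils read.table write.table
NULL

NT_ALPHABET <- c("A", "C", "G", "T", "U")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
# PSI-BLAST ASCII column order; all PSSM matrices use it.
PSSM_COLUMNS <- AA_ALPHABET

#' Read sequences from a FASTA file
#'
#' Reads a FASTA file and returns a validated, uppercased set of sequences.
#' Nucleotide records may contain A, C, G, T or U; protein records the 20
#' standard amino-acid letters. Any other residue raises an error naming the
#' record and the 1-based offending position (coordinates in all file formats
#' are 1-based; internal indexing is R's native 1-based indexing).
#'
#' @param path Path to a FASTA file.
#' @param molecule `"nucleotide"` or `"protein"`.
#' @param permissive For proteins only: if `TRUE`, the ambiguity codes
#'   B, Z, X, U, O are tolerated and contribute zero in every encoder
#'   (they are recorded but carry no hydropathy value). Default `FALSE`.
#' @return A named character vector of residue strings (names are record
#'   ids), with attribute `molecule`. For nucleotides an attribute
#'   `original` keeps the letters as read (U is mapped to T in the working
#'   copy so DNA and RNA share one K-tuple property table).
#' @export
read_fasta <- function(path, molecule = c("nucleotide", "protein"),
                       permissive = FALSE) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  res <- toupper(as.character(set))
  names(res) <- ids
  validate_residues(res, molecule, permissive = permissive)
  if (molecule == "nucleotide") {
    out <- chartr("U", "T", res)
    attr(out, "original") <- res
  } else {
    out <- res
  }
  attr(out, "molecule") <- molecule
  out
}

validate_residues <- function(seqs, molecule, permissive = FALSE) {
  alphabet <- if (molecule == "nucleotide") NT_ALPHABET else AA_ALPHABET
  if (molecule == "protein" && permissive)
    alphabet <- c(alphabet, "B", "Z", "X", "U", "O")
  for (id in names(seqs)) {
    s <- seqs[[id]]
    if (nchar(s) < 1L) stop("empty sequence for record '", id, "'")
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% alphabet)
    if (length(bad))
      stop("invalid ", molecule, " residue '", ch[bad[1]], "' in record '",
           id, "' at position ", bad[1])
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]; original letters (e.g. U in RNA aptamers) are
#' restored if present.
#'
#' @param seqs Named character vector as returned by [read_fasta()].
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  orig <- attr(seqs, "original")
  out <- if (!is.null(orig)) orig else seqs
  set <- Biostrings::BStringSet(setNames(as.character(out), names(out)))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a position-specific scoring matrix
#'
#' Accepts either the PSI-BLAST `-out_ascii_pssm` dialect (header lines, row
#' index + residue letter + 20 log-odds columns + trailing statistics) or a
#' plain whitespace-separated L x 20 table. The dialect is auto-detected.
#' Columns are returned in PSI-BLAST order
#' (A R N D C Q E G H I L K M F P S T W Y V).
#'
#' @param path Path to the PSSM file.
#' @param protein_id Optional id stored as an attribute.
#' @param expected_length If given, the row count is checked against it.
#' @return An L x 20 numeric matrix with `colnames` in canonical order.
#' @export
read_pssm <- function(path, protein_id = NULL, expected_length = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ascii_rows <- grep("^\\s*[0-9]+\\s+[A-Za-z*]\\s+-?[0-9]", lines)
  if (length(ascii_rows) > 0L) {
    mat <- parse_pssm_ascii(lines[ascii_rows], path)
  } else {
    mat <- parse_pssm_plain(lines, path)
  }
  colnames(mat) <- PSSM_COLUMNS
  if (!is.null(expected_length) && nrow(mat) != expected_length)
    stop("PSSM '", path, "' has ", nrow(mat), " rows but protein length is ",
         expected_length)
  if (!is.null(protein_id)) attr(mat, "protein_id") <- protein_id
  mat
}

parse_pssm_ascii <- function(rows, path) {
  vals <- lapply(rows, function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    # tok: position, residue letter, then >= 20 numbers (log-odds first)
    num <- suppressWarnings(as.numeric(tok[-(1:2)]))
    num <- num[!is.na(num)]
    if (length(num) < 20L)
      stop("PSSM '", path, "': expected 20 score columns, found ",
           length(num), " in row '", trimws(l), "'")
    num[1:20]
  })
  do.call(rbind, vals)
}

parse_pssm_plain <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("PSSM '", path, "' is empty")
  vals <- lapply(lines, function(l) {
    num <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (anyNA(num) || length(num) != 20L)
      stop("PSSM '", path, "': expected 20 numeric columns, found ",
           sum(!is.na(num)), " in row '", trimws(l), "'")
    num
  })
  do.call(rbind, vals)
}

#' Read a per-residue disorder-score track
#'
#' Accepts one score per line, or two whitespace-separated columns
#' (1-based residue index, score). Scores must lie in \[0, 1\].
#'
#' @param path Path to the track file.
#' @param protein_id Optional id stored as an attribute.
#' @param expected_length If given, the track length is checked against it.
#' @return Numeric vector of length L.
#' @export
read_disorder_track <- function(path, protein_id = NULL,
                                expected_length = NULL) {
  if (!file.exists(path)) stop("disorder track not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("disorder track '", path, "' is empty")
  scores <- vapply(seq_along(lines), function(i) {
    tok <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(tok) || !length(tok) %in% c(1L, 2L))
      stop("disorder track '", path, "', line ", i,
           ": expected 1 or 2 numeric columns")
    tok[length(tok)]
  }, numeric(1))
  bad <- which(scores < 0 | scores > 1)
  if (length(bad))
    stop("disorder track '", path, "', line ", bad[1], ": score ",
         scores[bad[1]], " outside [0, 1]")
  if (!is.null(expected_length) && length(scores) != expected_length)
    stop("disorder track '", path, "' has ", length(scores),
         " scores but protein length is ", expected_length)
  if (!is.null(protein_id)) attr(scores, "protein_id") <- protein_id
  scores
}

#' Read an aptamer-protein pair table
#'
#' TSV with header `aptamer_id	protein_id	label`; labels may be
#' `1`/`0` or `positive`/`negative`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `aptamer_id`, `protein_id` and integer
#'   `label` (1 = interacting).
#' @export
read_pair_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "")
  need <- c("aptamer_id", "protein_id", "label")
  if (!all(need %in% names(df)))
    stop("pair table must have columns: ", paste(need, collapse = ", "))
  lab <- tolower(as.character(df$label))
  ok_pos <- lab %in% c("1", "positive")
  ok_neg <- lab %in% c("0", "negative")
  if (any(!(ok_pos | ok_neg)))
    stop("pair table labels must be 1/0 or positive/negative; got '",
         lab[which(!(ok_pos | ok_neg))[1]], "'")
  df$label <- as.integer(ok_pos)
  df[need]
}

#' Assemble a pair dataset
#'
#' Bundles a pair table with its sequence, PSSM and disorder stores, checking
#' that every id resolves and every per-protein track matches the protein
#' length. Proteins without a PSSM file get a zero L x 20 matrix (the
#' standard no-homolog fallback) with a warning.
#'
#' @param pairs data.frame from [read_pair_table()] (or equivalent).
#' @param aptamers,proteins Named residue-string vectors ([read_fasta()]).
#' @param pssm Named list of L x 20 matrices, or a directory containing one
#'   `<protein_id>.pssm` file per protein.
#' @param disorder Named list of numeric tracks, or a directory containing
#'   one `<protein_id>.txt` file per protein.
#' @return An object of class `pair_dataset` with elements `pairs`,
#'   `aptamers`, `proteins`, `pssm`, `disorder`, `n_pos`, `n_neg`.
#' @export
pair_dataset <- function(pairs, aptamers, proteins, pssm = NULL,
                         disorder = NULL) {
  miss_a <- setdiff(pairs$aptamer_id, names(aptamers))
  if (length(miss_a)) stop("aptamer id(s) not loaded: ",
                           paste(utils::head(miss_a, 5), collapse = ", "))
  miss_p <- setdiff(pairs$protein_id, names(proteins))
  if (length(miss_p)) stop("protein id(s) not loaded: ",
                           paste(utils::head(miss_p, 5), collapse = ", "))
  prot_ids <- unique(pairs$protein_id)
  if (is.character(pssm) && length(pssm) == 1L && dir.exists(pssm)) {
    dir <- pssm
    pssm <- lapply(setNames(prot_ids, prot_ids), function(id) {
      f <- file.path(dir, paste0(id, ".pssm"))
      if (!file.exists(f)) return(NULL)
      read_pssm(f, protein_id = id, expected_length = nchar(proteins[[id]]))
    })
  }
  if (is.character(disorder) && length(disorder) == 1L &&
      dir.exists(disorder)) {
    dir <- disorder
    disorder <- lapply(setNames(prot_ids, prot_ids), function(id) {
      f <- file.path(dir, paste0(id, ".txt"))
      if (!file.exists(f)) stop("missing disorder track for protein '", id,
                                "' (expected ", f, ")")
      read_disorder_track(f, protein_id = id,
                          expected_length = nchar(proteins[[id]]))
    })
  }
  if (!is.null(pssm)) {
    for (id in prot_ids) {
      if (is.null(pssm[[id]])) {
        warning("no PSSM for protein '", id,
                "'; substituting a zero matrix", call. = FALSE)
        pssm[[id]] <- matrix(0, nchar(proteins[[id]]), 20,
                             dimnames = list(NULL, PSSM_COLUMNS))
      }
    }
  }
  n_pos <- sum(pairs$label == 1L)
  n_neg <- sum(pairs$label == 0L)
  stopifnot(n_pos + n_neg == nrow(pairs))
  structure(list(pairs = pairs, aptamers = aptamers, proteins = proteins,
                 pssm = pssm, disorder = disorder,
                 n_pos = n_pos, n_neg = n_neg),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat("pair_dataset:", nrow(x$pairs), "pairs (", x$n_pos, "positive /",
      x$n_neg, "negative ),", length(x$aptamers), "aptamers,",
      length(x$proteins), "proteins\n")
  invisible(x)
}

#' Minimum sequence length of a corpus
#'
#' The shortest sequence length in a collection. This corpus statistic
#' parameterizes the encoders: the number of sequence-order correlation
#' factors for aptamers (lambda = L_min - K) and the number of disorder
#' autocovariance lags for proteins (L_min - 1).
#'
#' @param sequences Named character vector of residue strings.
#' @return A positive integer.
#' @export
corpus_min_length <- function(sequences) {
  if (length(sequences) == 0L) stop("empty sequence collection")
  min(nchar(sequences))
}
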