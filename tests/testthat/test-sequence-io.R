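test_that("FASTA reading validates, uppercases, and maps U to T", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a1 some description", "acgu", ">a2", "ACGT"), f)
  seqs <- read_fasta(f, "nucleotide")
  expect_named(seqs, c("a1", "a2"))
  expect_identical(unname(seqs["a1"]), "ACGT")          # U -> T internally
  expect_identical(unname(attr(seqs, "original")["a1"]), "ACGU")
  expect_equal(nchar(seqs[["a1"]]), 4)

  writeLines(c(">p", "MKV"), f)
  prot <- read_fasta(f, "protein")
  expect_identical(unname(prot["p"]), "MKV")

  writeLines(c(">bad", "ACGX"), f)
  expect_error(read_fasta(f, "nucleotide"), "position 4")
  writeLines(c(">amb", "MKBV"), f)
  expect_error(read_fasta(f, "protein"), "position 3")
  expect_silent(read_fasta(f, "protein", permissive = TRUE))
})

test_that("FASTA round-trip preserves ids and residues exactly", {
  set.seed(11)
  ids <- paste0("s", 1:8)
  seqs <- setNames(vapply(sample(8:30, 8, TRUE), random_nt, ""), ids)
  attr(seqs, "molecule") <- "nucleotide"
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f, "nucleotide")
  expect_identical(names(back), ids)
  expect_equal(unname(back), unname(seqs), ignore_attr = TRUE)
})

test_that("both PSSM dialects parse to the same canonical matrix", {
  set.seed(3)
  m <- matrix(sample(-10:10, 52 * 20, TRUE), 52, 20)
  plain <- withr::local_tempfile(fileext = ".pssm")
  write.table(m, plain, row.names = FALSE, col.names = FALSE)
  got_plain <- read_pssm(plain)
  expect_equal(dim(got_plain), c(52, 20))
  expect_equal(unname(got_plain), m, ignore_attr = TRUE)
  expect_identical(colnames(got_plain),
                   strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])

  # PSI-BLAST -out_ascii_pssm dialect: headers, row index + residue,
  # 20 log-odds + 20 percentages + 2 statistics, trailing K/Lambda block
  ascii <- withr::local_tempfile(fileext = ".pssm")
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(sprintf("%5d %s", i, "M"),
            sprintf("%3d", m[i, ]), sprintf("%4d", rep(0, 20)),
            " 0.36 0.09"), collapse = " ")
  }, "")
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste(c("    ", aa, aa), collapse = "  "), rows, "",
               "                      K         Lambda",
               "Standard Ungapped    0.1347     0.3179"), ascii)
  got_ascii <- read_pssm(ascii)
  expect_equal(unname(got_ascii), m, ignore_attr = TRUE)

  bad <- withr::local_tempfile()
  write.table(m[, 1:19], bad, row.names = FALSE, col.names = FALSE)
  expect_error(read_pssm(bad), "20")
  expect_error(read_pssm(plain, expected_length = 51), "52 rows")
})

test_that("disorder tracks accept 1- and 2-column text and check range", {
  f <- withr::local_tempfile()
  writeLines(c("1 0.9", "2 0.1"), f)
  expect_equal(read_disorder_track(f), c(0.9, 0.1))
  writeLines(rep("0.5", 52), f)
  expect_equal(read_disorder_track(f), rep(0.5, 52))
  writeLines(c("1 0.5", "2 0.2", "3 1.2"), f)
  expect_error(read_disorder_track(f), "outside \\[0, 1\\]")
  writeLines(rep("0.4", 10), f)
  expect_error(read_disorder_track(f, expected_length = 12), "10 scores")
})

test_that("pair tables accept both label vocabularies", {
  f <- withr::local_tempfile()
  writeLines(c("aptamer_id\tprotein_id\tlabel",
               "a1\tp1\tpositive", "a2\tp1\t0", "a3\tp2\t1"), f)
  pairs <- read_pair_table(f)
  expect_equal(pairs$label, c(1L, 0L, 1L))
  writeLines(c("aptamer_id\tprotein_id\tlabel", "a1\tp1\tmaybe"), f)
  expect_error(read_pair_table(f), "maybe")
})

test_that("pair_dataset checks ids, counts classes, and substitutes zero PSSMs", {
  ds <- small_corpus(n_pos = 5, n_neg = 15, seed = 2)
  expect_equal(ds$n_pos + ds$n_neg, nrow(ds$pairs))
  expect_equal(ds$n_pos, 5)
  pairs_bad <- ds$pairs
  pairs_bad$aptamer_id[1] <- "ghost"
  expect_error(pair_dataset(pairs_bad, ds$aptamers, ds$proteins), "ghost")
  pssm_missing <- ds$pssm
  pssm_missing[[1]] <- NULL
  expect_warning(
    ds2 <- pair_dataset(ds$pairs, ds$aptamers, ds$proteins,
                        pssm = pssm_missing, disorder = ds$disorder),
    "zero matrix")
  id <- setdiff(names(ds$pssm), names(pssm_missing))
  expect_true(all(ds2$pssm[[id]] == 0))
})

test_that("corpus_min_length returns the minimum residue count", {
  expect_equal(corpus_min_length(c(a = "ACGTACG")), 7)
  expect_equal(corpus_min_length(c(a = strrep("A", 8), b = strrep("C", 10),
                                   c = strrep("G", 30))), 8)
  expect_error(corpus_min_length(character()), "empty")
})
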