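Package: aptensemble
Title: Aptamer-Protein Interaction Prediction with Hybrid Sequence
    Features and a Partition-Ensemble Random Forest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts aptamer-protein interacting pairs from sequence
    alone. Aptamers (DNA/RNA) are encoded with pseudo K-tuple nucleotide
    composition (K = 2 and 3); target proteins are encoded with low-frequency
    discrete cosine transform coefficients of hydropathy signals, bi-gram
    transition features of PSI-BLAST position-specific scoring matrices, and
    autocovariance plus segment summaries of per-residue intrinsic disorder
    scores. Features are ranked with Relief and pruned by incremental feature
    selection maximizing cross-validated Youden's index. Classification uses
    an ensemble of random forests, one per partition of the majority
    (negative) class, with averaged probabilities, designed for the 1:3 class
    imbalance typical of curated aptamer-protein pair collections. Includes
    readers for FASTA, PSI-BLAST ASCII PSSM and disorder-score tracks, a
    synthetic corpus generator with a tunable planted class signal, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
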