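---
title: "Predicting aptamer-protein interactions: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting aptamer-protein interactions: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptensemble)
```

`aptensemble` predicts whether an aptamer (single-stranded DNA/RNA) and a
protein interact, from sequence-derived features alone. This vignette is
the package's account of the science: the feature models and their
assumptions, the selection and classification procedure, every tunable
parameter with its default and rationale, what the synthetic corpus
generator does and does not emulate, and the numerical and design choices
made where more than one defensible option existed.

## The prediction problem

Curated aptamer-protein pair collections are imbalanced at roughly 1:3
(interacting : non-interacting). A single classifier trained on such data
buys specificity at the cost of sensitivity, which is why performance here
is always summarized by Youden's index `J = Sn + Sp - 1` alongside
accuracy and MCC: `J` is insensitive to the class ratio, and a balanced
`Sn`/`Sp` pair at a given `J` is preferred over an unbalanced one.

## Feature models

### Aptamers: pseudo K-tuple nucleotide composition

A sequence of length `L` over {A, C, G, T/U} is encoded, for K = 2 and
K = 3, by the `4^K` overlapping-tuple frequencies `f_u` (normalized by
`L - K + 1`) plus `lambda` sequence-order correlation factors. The j-th
factor averages, over all positions `i`, the mean squared difference of
the `N` standardized physicochemical property values between the tuples at
`i` and `i + j` (`N` = 6 dinucleotide properties for K = 2, 12
trinucleotide properties for K = 3). Frequencies and `omega`-weighted
factors are jointly normalized, so each PseKNC vector is non-negative and
sums to one; a homopolymer degenerates to an indicator vector because all
its tuple pairs are identical.

Assumptions: local composition and medium-range property correlation carry
binding-relevant signal; DNA and RNA are treated identically after mapping
U to T, so both share one property table. The mapping is a documented
choice — the property literature gives no separate RNA slot for the
encoding used here.

The K-tuple property tables shipped under `inst/extdata/` are **synthetic
stand-ins** (hence the `_synthetic` suffix): complementary-symmetric
helical step parameters (twist, tilt, roll, shift, slide, rise) in
realistic B-DNA ranges for dinucleotides, and, for trinucleotides, the 12
values formed by the step parameters of the two constituent dinucleotide
steps. Users with a preferred published compilation can drop in their own
TSV via `load_property_table(path)`. Two facts make this substitution
benign for everything the package asserts: each property is standardized
to mean 0 / population sd 1 across the `4^K` tuples at load (so all
downstream math is invariant to affine rescaling of the raw values), and
no shipped test or reported quantity depends on specific raw property
values — only on the structure of the encoding.

### Proteins: DCT of hydropathy signals

The per-residue hydrophobicity and hydrophilicity signals are transformed
with the orthonormal type-II discrete cosine transform and the 52
low-frequency coefficients per scale are kept (104 features). The DCT
compresses the global shape and periodicity of the hydropathy profile into
a fixed-length descriptor; orthonormality gives Parseval's identity, which
the tests use as an internal consistency check. The scales are
Kyte-Doolittle and Hopp-Woods — the field's most common pairing; the
sources never constrain this choice, so both are replaceable via
`load_hydropathy_scales(path)`. Each scale is standardized over the 20
residues so the two blocks are comparable in magnitude.

### Proteins: bi-gram PSSM

From an `L x 20` PSI-BLAST profile `P`, the 400 features
`B[m, n] = sum_i P[i, m] * P[i + 1, n]` summarize evolutionary
substitution preferences of *adjacent* positions. Raw log-odds are
squashed element-wise through the logistic function before the products
(default `pssm_normalize = "sigmoid"`), because raw integer products are
scale-unstable and dominated by extreme entries; `"none"` retains raw
values for users who want the literal products. A protein with no
detectable homologs gets a zero profile (the standard fallback, applied
with a warning), which under `"none"` yields an all-zero bi-gram block and
leaves the other blocks untouched.

### Proteins: intrinsic disorder

Per-residue disorder scores in [0, 1] (e.g. from VSL2-style predictors,
consumed as plain text) are summarized by 51 autocovariance terms
`AC_lag = (1/(L - lag)) * sum (d_i - dbar)(d_{i+lag} - dbar)`, lag =
1...51, plus 8 summaries: mean, population sd, the numbers of disordered
and ordered segments (maximal runs at or above / below the 0.5 threshold),
and the minimal/maximal lengths of each segment class, with `min = max =
0` as the explicit sentinel for an absent class. Population (divide by
`L`) rather than sample normalization matches the `1/(L - lag)`
convention of the autocovariance itself.

## Parameter reference

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `omega` | 0.5 | weight, > 0 | conventional PseKNC weighting of order vs composition |
| `lambda2`, `lambda3` | `L_min - K` of the aptamer corpus (6 and 5 at benchmark `L_min` = 8) | tiers | the largest lag every corpus sequence supports |
| `n_dct` | 52 per scale | coefficients | benchmark minimum protein length |
| `max_lag` | 51 | lags | `L_min - 1` at benchmark protein `L_min` = 52 |
| `pssm_normalize` | `"sigmoid"` | - | scale-stable products; `"none"` for literal sums |
| `threshold` | 0.5 | disorder score | binary convention of disorder predictors |
| `n_neighbors` | 10 | neighbours | common ReliefF practice; 1 reproduces the single-hit/miss rule |
| `step` (IFS) | 1 | features | one-by-one prefix growth; larger = coarser, cheaper sweep |
| `n_trees` | 500 | trees | stable probability forests; smaller values for quick sweeps |
| `mtry` | `sqrt(d)` | features/split | random-forest default for classification |
| `k` (CV) | 10 | folds | standard; stratified |
| decision threshold | 0.5, ties positive | probability | documented tie rule |

## Feature selection

`relief_rank()` scores features by nearest-hit/nearest-miss contrast:
range-normalized per-feature differences, Manhattan distance for the
neighbour search, all instances sampled, weights accumulated over
instances. Constant features get weight exactly 0; ranking is invariant to
affine rescaling of any feature; ties break by original column order.
`ifs_search()` then evaluates growing prefixes of the ranking with the
partition-ensemble cross-validation, holding one fold assignment fixed
across prefixes so the curve reflects features rather than fold noise, and
returns the prefix maximizing mean Youden's index — the smallest such
prefix on ties (parsimony; any other tie rule would be arbitrary).

## The partition ensemble

With `n_pos` positives and `n_neg >= n_pos` negatives, the negatives are
shuffled (seeded) and split into `N = floor(n_neg / n_pos)` parts, sizes
differing by at most one (the floor-plus-round-robin rule covers ratios
that do not divide evenly); each part plus all positives trains one
probability random forest, seeded per subset. Prediction averages the `N`
positive-class probabilities without weights. Cross-validation is
stratified (keeping every fold near the global class ratio), rebuilds the
partition *inside* each fold's training portion so no negative leaks
across the train/test boundary, and averages per-fold metrics; pooled
confusion counts are available behind `pooled = TRUE` for users who prefer
them. A metric with a zero denominator (e.g. MCC on a degenerate fold)
reports 0 with a warning rather than NaN.

## The synthetic corpus generator

`generate_corpus()` emulates all four input channels with a class signal
planted in each: GC-tilted aptamer composition, a fixed +/- PSSM column
bias, a raised latent disorder level (longer disordered segments), and a
mild hydrophobic tilt in protein composition, each scaled by
`effect_size`. The channel coefficients (0.25, 0.20, 0.15, 0.08
respectively) are fixed calibration constants chosen so that
`effect_size = 1` produces the intermediate regime where imbalance
correction matters (ensemble cross-validated `J` around 0.4 on a 1:3
corpus, comparable to real benchmark performance), `effect_size = 2` is
strong but imperfect, and `effect_size = 0` is an exact null with
identically distributed classes. Defaults follow the study conditions:
1:3 class ratio, aptamers of 8-40 nt, proteins of 52-120 aa.

What it does **not** emulate: real SELEX sequence biases, binding
thermodynamics, homology structure among proteins (every pair gets an
independent protein, so there is no shared-protein leakage to guard
against), realistic PSI-BLAST score correlations along a profile, or
predictor-specific disorder artifacts. Passing tests on this corpus
therefore demonstrate that the pipeline recovers a multi-channel planted
signal under the benchmark's class ratio and length regime — not that it
attains any particular performance on real aptamer data, which
additionally requires genuine PSSM and disorder inputs.

## Numerical choices and degenerate inputs

* Property and scale standardization use the population sd; a
  zero-variance property or scale is an error (it carries no contrast).
* `theta` factors and autocovariances are exact sums, checked against
  naive double/triple-loop oracles at 1e-10 in the tests.
* Sequences shorter than the configured `lambda` or `n_dct` raise errors
  naming the sequence; an optional zero-padding flag exists for the DCT
  only (exploratory use).
* Non-standard protein letters are rejected by default;
  `permissive = TRUE` maps B/Z/X/U/O to zero contribution in every
  encoder. Strictness surfaces data problems early.
* All randomness (shuffles, forests, folds, corpora) flows from explicit
  integer seeds; identical seeds give byte-identical outputs, which the
  round-trip and determinism tests assert.

## Problem sizes used by the shipped tests

The test suite exercises cross-validated ensembles on corpora of 40
positives / 120 negatives with 5-fold cross-validation and 100-tree
forests (10 seeds for the null calibration, 5 for the imbalance
contrast), and encoder oracles on hundreds of random small instances.
These sizes preserve the structural conditions that matter — the 1:3
ratio, hence `N = 3` partitions, and the benchmark length regime — while
keeping the full suite fast enough to run routinely; they are the
package's choice of scale, and larger corpora change only runtime, not
any asserted property.

## Known limitations

* The shipped K-tuple property tables are synthetic stand-ins (see above);
  results on real data should use a published compilation via the TSV
  hook.
* Relief here is the two-class variant; multi-class extensions are out of
  scope.
* The ensemble supports one base learner (random forest); probability
  calibration, cost-sensitive losses and oversampling schemes are
  deliberately out of scope.
* Real-data performance depends on externally produced PSSM and disorder
  tracks; the package consumes but does not generate them (no PSI-BLAST
  or disorder predictor is invoked).
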