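---
title: "Methods: a stacked ensemble for 4mC site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stacked ensemble for 4mC site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling choices behind `stack4mc`: the
two-layer stacked ensemble itself, the seven sequence encodings, the
dataset-construction rules, what the synthetic-data generator does and
does not emulate, and the numerical conventions used throughout.

## Data model

The atomic unit is a 41-nt DNA window over {A, C, G, T} with a cytosine
at the central position (position 21, 1-based; positions are 1-based in
all user-facing output and 0-free internally via R indexing). Windows of
any other length, windows with ambiguity codes (`N`, IUPAC codes, `U`)
and windows whose centre is not `C` are rejected rather than repaired:
the classifier's contract is strict ACGT, and silently converting or
trimming input would change the meaning of every position-indexed
feature. Non-strict FASTA import (`read_fasta(..., strict = FALSE)`)
exists for screening pipelines; it drops offenders and reports them
instead of guessing.

## The seven encodings

Each encoding is a deterministic pure function of the window with a
fixed, asserted dimension:

| encoding | dim  | content |
|----------|------|---------|
| Kmer     | 1364 | k = 1..5 substring frequencies, count/(41−k+1) |
| M6AMRFS  | 200  | 4-bit dinucleotide binary codes (160) + prefix dinucleotide frequencies (40) |
| RFHC     | 164  | chemical-class triple + cumulative base density per position |
| EIIP     | 64   | trinucleotide frequency × summed per-base pseudopotential |
| BPF      | 164  | per-position one-hot (A, T, G, C order) |
| DPCP     | 240  | dinucleotide frequency × 15 property values |
| TPCP     | 704  | trinucleotide frequency × 11 property values |

Conventions that were genuinely open and are fixed here:

* **k-mer normalization.** Frequencies (count divided by the number of
  overlapping windows, 41−k+1) rather than raw counts, so blocks of
  different k are on a common scale; each k-block sums to 1. The same
  overlapping-window denominators (40 for dinucleotides, 39 for
  trinucleotides) are used by EIIP, DPCP and TPCP.
* **Ordering.** All oligomer axes are lexicographic with A < C < G < T,
  and the property encodings are oligomer-major, property-minor. Any
  fixed order works; lexicographic makes matrices reproducible and easy
  to diff.
* **Dinucleotide binary code.** The published description of this
  encoding gives four worked examples (AT, AA, GG, AC) but not the rule.
  The per-base 2-bit code A = (0,0), C = (1,0), G = (1,1), T = (0,1),
  concatenated per dinucleotide, is the unique concatenative code
  consistent with all four examples; the test suite asserts those four
  tuples before any other use of the encoding.
* **Prefix quantities.** The prefix length |Y_j| in the local
  dinucleotide frequency, and the analogous normalizer in the RFHC
  density, are read as j (the length of the j-th prefix). This makes
  f_j = D/j and d_j proper frequencies in (0, 1] — every f_j lies in
  (0, 0.5] since at most ⌊j/2⌋ of the j−1 dinucleotides in a length-j
  prefix can coincide.
* **M6AMRFS concatenation order** is binary part first, frequency part
  second (200 = 160 + 40), matching the order in which the two halves
  are usually described.

### Physicochemical property tables

DPCP/TPCP require a 16 × 15 dinucleotide and a 64 × 11 trinucleotide
property matrix normalized to [0, 1]. The package does **not** ship a
curated physicochemical set: the bundled defaults
(`inst/extdata/*_properties_synthetic.tsv`) are clearly-labelled
synthetic placeholders — fixed pseudo-random values, min-max normalized —
that keep the pipeline self-contained and exercise the full code path.
Because every DPCP/TPCP column is the product of a constant and the
oligomer frequency, classification behaviour on synthetic data is
insensitive to the particular constants; biological interpretation of
individual DPCP/TPCP features, however, requires a curated table, which
users can supply through `read_property_table()` (delimited text, header
row, oligomer in the first column). All correctness tests use synthetic
identity/zero/random tables so that nothing depends on the placeholder
values.

## Dataset construction

* **Redundancy filtering** is greedy incremental clustering in input
  order at a Hamming-identity cutoff (fraction of equal positions).
  Purpose-built clustering tools compute word-filtered global alignment
  identities; for gap-free fixed-length windows Hamming identity is the
  same quantity without the alignment machinery, and the greedy
  keep-first rule reproduces the usual representative-selection
  behaviour. Retained sets are asserted pairwise non-redundant.
* **Cross-set filtering** removes negatives whose identity to any
  positive is *strictly* greater than the cutoff (default 0.6), so a
  negative at exactly 60% identity is retained.
* **Splits** are stratified per class: `floor(frac × n)` per class, or an
  explicit per-class count (`n_benchmark = 800` reproduces the
  800/800 + 180/180 partition of a 980 + 980 pool, where 800 is a round
  number slightly above floor(0.8 × 980) = 784). Repeats are seeded
  `seed + r − 1` so plans are reproducible individually and jointly.

## The synthetic generator

`generate_synthetic()` draws windows from a uniform ACGT background,
forces the centre to `C`, and plants class-specific motif blocks
independently with probability `effect_size`: positives get C runs at
positions 1–3 and 15–17 and a T run at 28–32; negatives get an A run at
1–3. These blocks mimic the position-specific composition enrichment
observed around genuine 4mC sites (C enriched upstream, T downstream of
positives; A runs in negatives). The default `effect_size = 0.8` gives a
strongly learnable but not degenerate signal; `effect_size = 0` makes the
classes exchangeable, which is used as a leakage control.

What the generator does **not** emulate: dinucleotide/k-mer dependence of
real genomic background, GC-content heterogeneity, near-duplicate windows
from repetitive DNA, label noise from modification-calling thresholds,
and any relationship between motif blocks. Passing tests on this data
therefore demonstrates that the pipeline is correct, leak-free and able
to recover planted positional signal — not that the reported accuracies
transfer to genomic 4mC data.

## The two-layer ensemble

* **Base layer.** 4 families × 7 encodings = 28 probability estimators:
  random forest (`randomForest`), extremely randomised trees (`ranger`
  with `splitrule = "extratrees"`, no bootstrap), gradient boosting
  (`xgboost`, logistic objective) and an RBF SVM (`e1071`, Platt-type
  probability calibration). Canonical model order is encoding-major
  (Kmer, M6AMRFS, RFHC, EIIP, BPF, DPCP, TPCP) × family-minor (RF, ERT,
  GB, SVM).
* **Hyperparameters.** `default_grids()` holds one fixed configuration
  per family (RF/ERT: 100 trees, √p candidate features; GB: 100 rounds,
  learning rate 0.1, depth 3; SVM: cost 1, gamma 1/p), sized for
  desk-scale runs. `full_grids()` exposes the wider ranges (trees
  100–500 and √p/log₂p; rounds {50, 100, 200} × rate {0.01, 0.1} × depth
  {3, 5}; cost 2⁻⁵..2⁵ × gamma 2⁻⁷..2³); multi-row grids are searched by
  stratified 10-fold CV accuracy with the best configuration refit on all
  data. Grid CV scores hard class calls (for the SVM, the margin sign):
  calibrated probabilities can disagree with the margin near 0.5 on tiny
  folds, and class accuracy is the quantity being optimized.
* **Out-of-fold stacking.** How the meta-layer's training inputs were
  obtained is the classic unstated detail of stacked ensembles; fitting
  the base models on all training data and predicting that same data
  would leak labels into the meta features. The package therefore uses
  k-fold out-of-fold generation (default 10): each training window's 28
  probabilities come from models whose training folds excluded it, with
  the fold bookkeeping kept on the feature matrix for auditing.
* **Meta layer and fusing.** The four families are refit on the
  28-dimensional probabilistic features. The fusing operator is the
  arithmetic mean of the four meta probabilities, thresholded at ≥ 0.5
  (ties positive). For four voters, probability averaging subsumes
  majority voting and cannot produce a 2–2 label tie; it is also
  monotone in each input, which is tested.
* **Determinism.** Every stochastic component draws from a sub-seed
  derived deterministically from the master seed and the model's
  (encoding, family, fold) coordinates; trees and boosting run
  single-threaded. Fixed seed + fixed data therefore reproduce
  byte-identical prediction tables.

## Evaluation conventions

* Accuracy is (TP+TN)/N. One widely-circulated printing of the metric
  set types the numerator as TP+FN; that form is a transcription error
  (it equals sensitivity-weighted prevalence, not accuracy) and a test
  asserts the implemented ACC diverges from it off the FN = TN diagonal.
* MCC uses the standard four-factor denominator and is reported as 0
  (with a warning) when a marginal vanishes.
* AUC is the rank-based Mann–Whitney statistic with average ranks for
  ties (equal to the trapezoidal ROC area); it is cross-checked against
  an independent ROC implementation in the tests.
* Position-wise enrichment uses two-proportion z-tests without
  continuity correction and Benjamini–Hochberg adjustment across the
  41 × 4 position-base tests; the constant centre position is flagged
  rather than tested.
* AUC vectors from repeated splits are compared with a two-tailed,
  equal-variance two-sample t-test by default; pairing across repeats is
  plausible but not obviously right, so `paired = TRUE` is a flag rather
  than the default.
* Repeated evaluation reports both layers explicitly: per-repeat metric
  rows plus mean ± sd, and the independent-set evaluator refuses any
  train/test id overlap outright.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
encodings are verified against brute-force oracles on 100 random
windows; the end-to-end signal-recovery run uses 400 windows per class
(80/20 split, 10 out-of-fold folds), the null-signal control 150 per
class, and the remaining behavioural tests use 10–1000 windows as
appropriate. These sizes were chosen so a full check runs in minutes on
one CPU while keeping binomial standard errors small enough for the
stated tolerances.

## Known limitations

* The synthetic benchmark is optimistic by construction (independent
  positions, exchangeable background); real-genome accuracy must be
  established on real windows.
* The bundled property tables are placeholders (see above).
* Greedy Hamming filtering is order-dependent, as is any greedy
  representative selection; feed it deterministically ordered input.
* The SVM's calibrated probabilities are themselves fit on internal CV
  folds and can be unstable on very small training sets; the other three
  families degrade more gracefully below ~20 windows per class.
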