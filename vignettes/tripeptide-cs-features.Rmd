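---
title: "Compressive tripeptide features: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressive tripeptide features: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trisense)
```

This vignette is the package's account of its science: what the feature
extractor computes, why the pieces are shaped the way they are, what the
synthetic benchmark does and does not establish, and the numerical
conventions a user may need to know.

## The encoding

A protein sequence over the 20-letter alphabet (alphabetical order,
`aa_alphabet`) is treated as a realization of a Markov process on
residues. The encoder records its order-2 transition behaviour as a
20 × 20 × 20 **transfer-frequency tensor**: sliding a three-residue
window with stride 1, tripeptide `XYZ` increments cell `(i, j, k)` where
`i, j, k` index `X, Y, Z` in the alphabet. A length-`L` chain yields
exactly `L − 2` counts, so for typical proteins (`L` a few hundred) at
most a few hundred of the 8000 cells are occupied. The tensor therefore
captures residue composition *and* local order while being sparse — the
property that makes random projection information-preserving.

The tensor is flattened **row-major** (first residue slowest, third
fastest: cell `(i, j, k)` at 0-based position `400 i + 20 j + k`) into
the signal `x` of length 8000. The choice of linearization is a
reproducibility convention, not a modelling decision: a Gaussian
measurement matrix is distribution-invariant under any fixed coordinate
permutation, so any fixed order gives statistically equivalent features.
`unflatten_signal()` inverts the flattening exactly.

The **raw integer counts**, not the probability normalization, form the
projected signal: the total `L − 2` carries sequence-length information,
and normalizing would discard it. `to_probability()` is provided for
model inspection only.

## The projection

`make_measurement_matrix(m, seed)` draws an `m × 8000` matrix of i.i.d.
zero-mean Gaussians and `project_signal()` computes `s = Φx`. Three
conventions matter:

* **Entry scale `1/sqrt(m)`.** Only "Gaussian" is prescribed by the
  method; the `1/m` variance is the standard compressive-sensing
  convention and makes `E‖Φv‖² = ‖v‖²`, so projected distances are
  comparable across `m`. Clustering is invariant to this global scale
  (asserted by a test), so the choice is cosmetic but recorded.
* **One matrix per experiment.** All sequences of a batch are projected
  with the same `Φ`; otherwise their features would not live in a common
  space. `extract_features()` enforces this, and permuting the input
  rows permutes the output rows identically.
* **Named PRNG.** Matrices are generated under Mersenne-Twister with
  inversion sampling regardless of the session's RNG settings, and the
  seed, scale and generator name are stored on every feature table and
  experiment, so runs reproduce bit-identically across machines.

The default compressed dimension is `m = 5`, the smallest dimension at
which the method is known to be insensitive to `m`; it is configurable
in `1 ≤ m < 8000`.

## Fuzzy c-means and the evaluation indices

The verification clusterer is standard Bezdek fuzzy c-means: centers
`c_k = Σ_i u_ik^m x_i / Σ_i u_ik^m`, memberships
`u_ik = 1 / Σ_j (d_ik/d_ij)^(2/(m−1))`, alternated until the objective
`Σ_i Σ_k u_ik^m d_ik²` decreases by less than `tol`. Defaults: fuzzifier
2.0, `tol = 1e-5`, `max_iter = 300`, random row-stochastic membership
initialization from a seeded PRNG, Euclidean distance. A sample that
coincides with a center receives membership 1 there (zero-distance
guard). The objective trajectory is stored and is non-increasing by
construction; every test run asserts this.

Feature sets are compared with:

* **scatter-trace ratio** `tr(Sw)/tr(Sb)`, computed by default on the
  *true* labels (the indices compare feature sets, pre-clustering; an
  option computes them on predicted labels for diagnostics). The
  implementation uses the trace-of-outer-product identity — sums of
  squared deviations — and satisfies
  `tr(Sw) + tr(Sb) = total scatter trace` to 1e-9. When every class mean
  coincides the ratio is undefined and a degenerate-separation error is
  raised rather than returning `Inf`.
* **partition entropy** with `log2` (so the ceiling is `log2 C` exactly
  and the crisp floor is 0), `0·log2 0 := 0`.
* **clustering accuracy** after aligning clusters to classes with the
  one-to-one assignment maximizing the confusion-matrix trace. Cluster
  indices from an unsupervised fit are arbitrary, so some alignment is
  unavoidable; the optimal bijection is found by exhaustive enumeration,
  which is exact and instantaneous for the class counts this method
  targets (an error is raised beyond C = 8). Ties in memberships break
  toward the lowest cluster index.

## The synthetic benchmark

Real benchmark corpora for this task are assembled ad hoc from protein
databases and are not redistributable in a lightweight package, so the
package carries a generator that plants exactly the statistical
structure the encoder is designed to detect: `make_class_models()`
builds per-class **order-2 Markov chains** (next residue conditioned on
the previous pair), and `simulate_dataset()` samples labeled sequences
from them.

A class model is drawn hierarchically:

1. a class residue-propensity vector `q ~ Dirichlet(0.3·1₂₀)`. The small
   concentration yields strongly skewed compositions, mimicking how real
   localization classes differ (membrane proteins enriched in
   hydrophobic residues, nuclear proteins in basic ones);
2. for each of the 400 pair contexts, a conditional next-residue
   distribution `~ Dirichlet(0.5·q)`. The small total concentration
   yields sharp, context-dependent transition preferences, the local
   regularity that distinguishes an order-2 signal from plain
   composition.

The class chain is blended with a shared uniform baseline:
`(1 − separation)·uniform + separation·class-specific`, so
`separation = 0` gives literally identical classes (a null dataset for
chance-level checks) and 1 gives independent classes. These
concentrations are deliberate: raw tripeptide counts carry multinomial
sampling noise of total variance ≈ `L − 2` per sequence, and diffuse
class models (e.g. unit-concentration Dirichlets) would plant a
between-class signal *below* that noise floor — no feature set could
separate such classes at realistic sequence lengths, which would say
nothing about the features. Default lengths are uniform on 150–350,
bracketing the bundled 265-residue example.

What the generator does **not** emulate: signal peptides, transmembrane
helices, domain architecture, phylogenetic correlation between
sequences, length–class correlation. Passing benchmarks on this
generator therefore shows that the pipeline detects planted
transition-statistic differences — not that it attains any particular
accuracy on real proteomes.

## The dimension sweep

Sensitivity to the compressed dimension is measured by
`dimension_sweep()`, which clusters one fixed dataset at
`m ∈ {5, 10, 15, 20, 30, 50}`. The sweep uses **leading-row prefixes of
a single master measurement matrix** (rescaled to the `1/sqrt(m)`
convention) rather than an independent draw per dimension. Rows of a
Gaussian matrix are i.i.d., so each prefix is itself a valid measurement
matrix; pairing the randomness this way is the variance-reduced design
for a dimension-effect experiment — with independent draws per `m`, an
unlucky low-dimensional draw occasionally costs several accuracy points
and the sweep measures draw luck rather than dimension. Accuracy indices
on a clustering of `n` samples are granular in steps of `1/n`.

## Problem sizes and budgets

The package's own test suite and the reproduction script run the full
pipeline at 100 sequences per class (2 and 3 classes), lengths 150–350,
`m = 10`, five replicate seeds for the discrimination and null checks,
and the six-dimension sweep above; unit tests use smaller sequence sets
(tens of sequences, lengths 30–120). These sizes give accuracy
granularity of 0.005–0.01 and complete in seconds while exercising every
stage at realistic sequence lengths.

## Known limitations

* Only `k = 3` (tripeptides) is implemented; the encoder does not
  generalize to other window widths.
* No signal reconstruction: the projection is used for discrimination
  only, and no recovery algorithm (or restricted-isometry verification)
  is provided.
* Fuzzy c-means is the only clusterer and Euclidean the only metric; the
  cluster count must be supplied (normally the number of distinct
  labels).
* Sequences shorter than 3 residues are valid FASTA input but cannot be
  encoded; they are rejected at extraction time, not at I/O time —
  alphabet validity and encodability are separate contracts.
* The optimal cluster-class alignment is enumerated, limiting accuracy
  computation to at most 8 classes.
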