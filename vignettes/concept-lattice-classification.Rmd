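---
title: "Concept-lattice classification: model, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept-lattice classification: model, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcaclass)
```

## The model

`fcaclass` classifies binary feature vectors with a concept lattice
rather than a parametric decision function. A formal context (G, M, I)
holds objects G (e.g. images), binary attributes M (e.g. thresholded
CNN embedding dimensions) and the incidence relation I. The two
derivation operators — attributes shared by a set of objects, objects
sharing a set of attributes — form a Galois connection, and the fixed
pairs (A, B) with A′ = B, B′ = A are the formal concepts. Ordered by
extent inclusion they form a complete lattice whose line (Hasse)
diagram is the interpretability surface of the model: each node is a
concept, and moving downward specializes (larger intents, smaller
extents).

Training proceeds in three steps. Feature vectors are deduplicated,
with the class labels of all duplicates kept as a per-unique-vector
multiset, so counts later reflect *images*, not unique vectors. The
lattice of the unique-vector context is enumerated. Finally every
concept with a non-empty extent is labeled with the class holding the
maximum duplicate-aware count over its extent. Prediction computes the
Hamming distance from the query vector to the intent indicator of each
*labeled* concept and returns the class of the nearest one. Unlabeled
(empty-extent) concepts — typically the lattice bottom — cannot supply
a class and are excluded as candidates.

Each labeled concept doubles as a rule *IF all attributes of the intent
THEN the majority class*, with support equal to the duplicate-aware
extent count and confidence equal to the majority share. Confidence-1
rules mark class-pure concepts and are the strongest statements the
model makes.

## Enumeration

Concepts are enumerated by Close-by-One (CbO) over attributes in
canonical (file) order. Candidate attributes are tried in descending
order inside the depth-first search so that the emission sequence is
exactly the lectic order of intents; the enumeration index is the
canonical concept index referenced by all downstream tie-breaking and
by the DOT/JSON exports. A brute-force oracle
(`brute_force_concepts()`) closes every subset of the smaller side of
the context (refusing beyond 16 elements) and is used in the test suite
to verify CbO on hundreds of random contexts; it is not used in
production paths. The covering order is obtained as the transitive
reduction of extent inclusion, computed with sparse boolean matrix
products (the `Matrix` package), which keeps lattice construction
comfortably fast at the scale the classifier targets (a few thousand
concepts). Concept counts are bounded by 2^min(|G|, |M|), and with the
16-attribute feature width the package is designed around, the worst
case of 2^16 concepts stays tractable.

`fca_fit(order = FALSE)` skips the covering-edge computation: the
classifier and the rule extractor only need the concepts themselves,
so repeated fits inside simulations avoid paying for edges they never
read. The fitted model still carries all concepts, and the Hasse
edges can be recovered later with `build_order()`.

## Tunable parameters and conventions

- **Binarization threshold** (`threshold`, default 0.5, unitless on the
  normalized scale). Continuous features are min-max normalized per
  feature to [0, 1] using *training* statistics, so one global threshold
  is meaningful across features; 0.5 is the midpoint of that range.
  Z-score normalization and raw thresholding are offered as options for
  data that is already standardized. The threshold and normalization
  are logged by the CLI on every run.
- **Strict inequality.** A bit is 1 exactly when the normalized value is
  strictly greater than the threshold. Whether equality at the
  threshold maps to presence is a genuine open choice; the strict
  reading is fixed here and documented so ties at the threshold are
  reproducible.
- **Held-out normalization.** Test data is transformed with the
  training statistics and, for min-max, clipped to [0, 1] first, so a
  held-out value below the training minimum maps to bit 0 and the
  transform never leaks test information. Constant training features
  carry no information; they are flagged and mapped to all-0 bits,
  which also avoids a zero denominator in min-max.
- **Majority tie-break.** When two classes tie in a concept's extent
  count, the smallest class label in canonical (sorted) order wins.
  Every such concept index is recorded in `tie_log`.
- **Distance tie-break.** When several labeled concepts are equally
  near a query, the one with the larger extent (more supporting unique
  vectors) wins, then the smaller canonical index. The number of
  concepts tied at the minimal distance is reported per prediction
  (`n_tied`), so users can audit how often arbitrariness mattered. Both
  tie policies are deterministic by design — an equally defensible
  alternative would be random resolution, but then repeated runs could
  disagree on individual predictions.
- **Canonical label order** is the sorted order of the distinct label
  strings. For the usual `"0"`/`"1"` encoding (0 = benign,
  1 = malignant) ties resolve toward `"0"`. Any number of classes is
  supported; the majority and nearest-intent steps generalize verbatim,
  and evaluation then reports one-vs-rest metrics per class.

## Metrics

`evaluate_classification()` reports accuracy, sensitivity, specificity
and F1 as percentages for a designated positive class (default `"1"`).
Zero-denominator ratios are reported as `NA`, never silently 0.
The arithmetic is cross-checked in the tests against an independent
confusion-matrix implementation on random label vectors.

## The synthetic generator

`generate_synthetic()` is the stand-in for features extracted from real
image models: each class owns a disjoint signature subset of attributes,
present with probability `p_signal` (default 0.9) within the class while
every other attribute fires with probability `p_noise` (default 0.05).
The defaults — 16 attributes, two classes, an even signature split —
mirror the feature width the classifier targets, so the lattice sizes
exercised by the tests match the intended operating regime. Continuous
mode draws class-conditional Gaussians (signature mean 1, background
mean 0, sd 0.25) so that min-max binarization at 0.5 recovers the
binary structure, exercising the full pipeline.

What passing these tests shows: the implementation recovers planted,
conditionally independent class signatures under Bernoulli noise, and
degrades monotonically as noise rises. What it does not show: real CNN
embeddings are correlated, class overlap is not symmetric, and feature
informativeness varies — so synthetic accuracy says nothing quantitative
about accuracy on real image features. The test-suite problem sizes
(12 attributes, 200 training and 100 test vectors, 10 seeds for the
recovery experiment) were chosen as the smallest scale at which the
planted-signature recovery is stable across seeds.

## Degenerate inputs and numerical choices

Empty attribute or object sets follow the lattice conventions: the
empty attribute set derives to all objects and vice versa, so the top
and bottom concepts always exist (they may coincide in a one-concept
lattice). Single-class training warns and predicts that class
everywhere. Duplicate identifiers, non-binary cells, NaN/Inf features
and schema mismatches are rejected at load time with the offending
row/column named. All computation is exact integer/boolean arithmetic;
there are no convergence or tolerance parameters anywhere in the model.

## Known limitations

- Lattice size grows with the number of *distinct* training vectors and
  can approach 2^min(|G|, |M|); beyond roughly 20 attributes the fit
  should be preceded by feature selection.
- Incremental insertion of new training data is not implemented; refit
  from scratch.
- No probabilistic outputs: predictions are hard labels with distances,
  and ROC-style analyses do not apply.
- Conceptual scaling beyond the single global threshold (per-feature
  thresholds, multi-interval scaling) is out of scope.
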