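# fcaclass

Interpretable classification with formal concept lattices.

`fcaclass` is for analysts who need a classifier whose every decision can
be read off a diagram — for example when screening histopathology images
with high-level features extracted from a CNN, where a black-box
prediction is not enough. Instead of fitting weights, it organizes the
training data into a *concept lattice* and classifies by proximity to the
lattice's concepts, so every prediction is traceable to a named set of
features and the training images that share them.

## The method

A **formal context** is a triple (G, M, I): objects G (images), binary
attributes M (presence/absence features), and an incidence relation
I ⊆ G × M. The derivation operators

- A′ = { m ∈ M : g I m for all g ∈ A }  (attributes common to objects A)
- B′ = { g ∈ G : g I m for all m ∈ B }  (objects having all attributes B)

form a Galois connection. A **formal concept** is a pair (A, B) with
A′ = B and B′ = A; concepts ordered by extent inclusion form a complete
lattice, drawn as a Hasse diagram.

The classifier:

1. **Deduplicate** training vectors, keeping the class labels of all
   duplicates as a multiset per unique vector.
2. **Enumerate** all concepts of the context over the unique vectors
   (Close-by-One algorithm) and label each concept whose extent is
   non-empty with the majority class of the training images in its
   extent (duplicate-aware counts; ties broken toward the smallest class
   label and logged).
3. **Predict** a new binary vector x by the Hamming distance
   d(x, B) = |{ m : x_m ≠ 1[m ∈ B] }| to every labeled concept intent B;
   the nearest concept's class is the prediction (ties broken toward the
   larger extent, then the smaller concept index, with the tie count
   reported).

Each labeled concept also reads as a rule *IF intent THEN class* with
duplicate-aware support and confidence. Continuous features are first
min-max normalized per feature and thresholded with one global cutoff
(default 0.5, strict `>`).

## Worked example

The package ships the classic 6-image, 4-attribute context
(`inst/extdata/example_context.csv`):

```r
library(fcaclass)
ctx <- read_context(system.file("extdata/example_context.csv", package = "fcaclass"))
derive_extent(ctx, c("a", "b"))
#> [1] "2" "3" "4" "5"
derive_extent(ctx, c("a", "b", "c"))
#> [1] "5"
lat <- build_order(ctx)
lat
#> Concept lattice: 6 concepts, 7 covering edges (context 6x4)
```

The six concept intents are {a}, {a,b}, {a,c}, {a,b,d}, {a,b,c},
{a,b,c,d}; the concept ({5}, {a,b,c}) sits below the concepts with
intents {a}, {a,b} and {a,c}. Fitting with class labels
`1→0, 2→1, 3→1, 4→1, 5→1, 6→0`:

```r
m <- fca_fit(ctx, labels = c(0, 1, 1, 1, 1, 0))
extract_rules(m)
#>   concept_index intent class support confidence
#> 1             3    a,b     1       4  1.0000000
#> 2             4  a,b,d     1       1  1.0000000
#> 3             5  a,b,c     1       1  1.0000000
#> 4             1      a     1       6  0.6666667
#> 5             2    a,c     0       2  0.5000000
predict(m, matrix(c(1, 1, 0, 0), 1, dimnames = list("q", c("a", "b", "c", "d"))))
#>   object predicted_label concept_index distance n_tied
#> 1      q               1             3        0      1
```

The rule `{a,b} → 1` has confidence 1: all four training images with
attributes a and b are class 1, so the test vector (1,1,0,0) is class 1
at Hamming distance 0. The concept with intent {a,c} (extent {5, 6}, one
image per class) is a recorded majority tie, resolved to class 0.

A command-line wrapper covers the whole workflow
(`lattice`, `binarize`, `fit`, `predict`, `evaluate`, `rules`, `synth`,
`export-dot`):

```sh
Rscript inst/cli/fca.R lattice --input inst/extdata/example_context.csv --dot lat.dot
```

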