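Package: fcaclass
Title: Interpretable Classification with Formal Concept Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Formal concept analysis (FCA) tools for interpretable
    classification of binarized feature data, such as high-level features
    extracted from histopathology images. Builds formal contexts from
    binary or thresholded continuous feature matrices, enumerates all
    formal concepts with the Close-by-One algorithm, constructs the
    concept (Hasse) lattice, labels concepts by duplicate-aware majority
    class, classifies new instances by minimal Hamming distance to
    concept intents, and extracts human-readable if-then rules with
    support and confidence. Includes Burmeister CXT and CSV context I/O,
    Graphviz DOT export of labeled line diagrams, confusion-matrix
    metrics, a synthetic data generator with known class structure, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr,
    knitr
Config/testthat/edition: 3
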