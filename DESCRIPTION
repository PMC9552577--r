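Package: quantmind
Title: Quantum-Cognition Models of Mental Representation and Modes of Thought
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A labeled finite-dimensional Hilbert-space toolkit for
    quantum-cognition modeling of mental representations. Concepts are
    superposition states over feature bases; conceptual change is modeled by
    elaboration operators, context projections, tensor-product combination of
    unintegrated knowledge, and Born-rule measurement with collapse. On top of
    the algebra the package computes three mode-of-thought measures -
    abstractness, divergence, and context-specificity - and provides a
    trajectory engine that replays conceptual-change case studies (including
    the classic children's mental models of the shape of the Earth) as ordered
    operator applications, emitting qualitative arrow tables of how each
    measure shifts at every step. A seeded synthetic generator produces random
    concept spaces, contexts, and trajectories for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
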