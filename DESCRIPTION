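Package: mrseqopt
Title: Simulation-Driven Optimization of Cartesian MRI Sequences from a Domain-Specific Language
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to describe Cartesian MRI pulse sequences and clinical
    optimization requirements in two small domain-specific languages, simulate
    the sequences on digital brain-tissue phantoms with a tissue-level
    isochromat (Bloch) engine, score reconstructions with twelve image-quality
    metrics (tissue contrasts, tissue SNR, ghosting, sharpness, homogeneity,
    motion and distortion sensitivity, acquisition time), learn per-metric
    regression surrogates (support vector regression, k-nearest neighbours,
    random forests) on a simulated training grid, and search the sequence space
    with a penalty-based evolutionary algorithm with candidate repair, returning
    the optimized sequence as DSL text.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    jsonlite,
    yaml,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
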