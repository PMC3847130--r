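Package: epso
Title: Enhanced Binary Particle Swarm Optimization for Gene Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Wrapper gene selection for high-dimensional expression data by
    binary particle swarm optimization. Implements an enhanced binary PSO
    (EPSO) that replaces the per-dimension velocity vector with a scalar,
    non-negative particle speed driven by a bit-vector distance, a steepened
    sigmoid transfer function, and an inverted bit-update rule, so that the
    probability of selecting any gene never exceeds one half and the search
    concentrates on small subsets. The conventional binary PSO (BPSO) is
    included as the baseline. Fitness is leave-one-out cross-validated
    accuracy of an RBF-kernel support vector machine on the selected genes,
    combined with a subset-size reward. Also provides entropy-based
    gain-ratio pre-ranking of genes, a synthetic expression-data generator
    with planted informative genes, delimited-text input/output, and
    repeated-run aggregation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
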