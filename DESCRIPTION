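Package: plinet
Title: Phase-Lag-Index Brain Networks and Metabolite Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resting-state EEG functional connectivity analysis built on the
    phase lag index (PLI): zero-phase FIR preprocessing into 2-s epochs,
    Hilbert instantaneous phases, per-band PLI matrices over the 20 canonical
    10-20 electrodes, proportional sparsity thresholding into binary graphs,
    and the four global graph-theory metrics (characteristic path length,
    clustering coefficient, global and local efficiency) over a 36-point
    sparsity grid. Group comparison with pooled t-tests, Benjamini-Hochberg
    FDR, Cohen's d, threshold averaging, and a permutation network-based
    statistic; metabolite screening by PLS-DA variable importance in
    projection (VIP > 1 and p < 0.05) with fold changes; and Spearman
    correlation of metabolite levels and depression scores against network
    topology across the sparsity grid. Includes a synthetic-cohort generator
    with analytically known phase-lag coupling and planted metabolite
    effects, so every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mixOmics,
    withr,
    jsonlite
Config/testthat/edition: 3
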