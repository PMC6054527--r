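Package: placeripple
Title: Place-Cell, Sharp-Wave-Ripple and Coactivity Analysis for Linear-Track Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal CA1 tetrode recordings on linear
    tracks with flanking rest sessions. Builds per-trajectory firing rate curves
    and Skaggs spatial information, detects place fields and rate-curve
    stability, fits theta phase precession by optimal linear and
    circular-linear regression, detects sharp-wave ripples in rest LFP with
    sd-relative thresholds, computes normalized pairwise cross-correlograms and
    the within-ripple coactivity statistic, and runs group-level comparisons
    including an equalized downsampling analysis. Ships a synthetic-data
    generator that emulates such recordings (Gaussian-tuned precessing place
    cells, ripple-bearing rest LFP, controlled pairwise coincidence injection)
    so every stage is verifiable against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    yaml,
    arrow,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
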