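Package: tagwave
Title: Transcriptional Waves, Regulator Influences and Flux-Balance
    Knockdown Screening for Starvation-Induced Lipid Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for nitrogen-starvation expression time courses
    in microalgae: log2-ratio filtering of FPKM trajectories against the
    pre-starvation reference, temporal ordering of co-regulated transcript
    modules into monotonic and transient transcriptional waves with
    minute-resolution twofold-crossing timestamps and early/mid/late stage
    labels, inference of time-lagged transcriptional-regulator influences on
    modules from smoothed, max-normalized profiles, and a flux balance
    analysis knockdown screen that ranks metabolic genes by the predicted
    triacylglycerol yield per unit biomass (rho). Includes a synthetic-data
    generator with planted ground truth and hand-solvable toy metabolic
    models so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
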