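Package: barrelgap
Title: Fourier Quantification of Intrinsic Optical Signals and the
    Adaptive Gap-Cross Tactile Learning Assay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two complementary measurements of whisker-mediated
    touch in mice. First, per-pixel Fourier extraction of the stimulus-locked
    fractional reflectance change (dR/R) from intrinsic-signal optical
    imaging stacks of barrel cortex, with threshold-curve quantification of
    the responsive region and a genotype comparison. Second, a discrete-event
    reimplementation of the closed-loop gap-cross assay: the
    exploration/adjustment state machine, sensor-based trial classification
    and the adaptive gap-distance algorithm, driven by a generative
    behavioral agent with genotype-specific learning. A statistics layer
    aggregates trial logs into session-block success tables and runs the
    block-by-distance repeated-measures ANOVA and between-genotype
    improvement comparison. Synthetic phantom stacks and simulated cohorts
    with known ground truth make every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
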