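Package: nanosip
Title: Stable-Isotope-Probing Analysis of NanoSIMS Ion Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multi-channel NanoSIMS ion-count image
    stacks from stable-isotope-probing (13C/15N) experiments on phototrophic
    biofilms: plane summation, per-pixel isotope ratios and delta values
    against VPDB/AIR references, log-threshold segmentation of autotroph and
    heterotroph populations with overlap-exclusion rules, per-cell and
    per-pixel enrichment statistics with rank tests and confidence ellipses,
    and deterministic cividis rendering with CIECAM02-UCS edge fading.
    Companion bulk assays are included (two-point IRMS delta calibration with
    carryover screening, qPCR standard-curve genome counting with Welch
    tests, and peptide-count normalization), together with a synthetic-scene
    generator that renders ground-truth biofilm geometries into Poisson
    ion-count stacks so the whole pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    EBImage
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
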