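Package: rbclesion
Title: Optical-Tweezers Analysis of the Red Blood Cell Storage Lesion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell biophysics of stored red blood cells measured with
    optical tweezers: per-cell zeta potential by Smoluchowski inversion of
    terminal-velocity-versus-field sweeps, per-cell apparent elasticity from a
    wall-corrected drag/elastic force balance on elongation-versus-velocity
    sweeps, and cohort-level storage-time statistics (day means with standard
    errors, two-tailed Wilcoxon rank-sum comparisons, percent-change headlines,
    and reactive-oxygen-species percent-positive kinetics). Includes video-track
    reduction (terminal velocity by least squares, cell length by segmentation
    and equivalent-ellipse moments), a calibrated synthetic-data generator for
    cohorts, sweeps, image stacks and flow-cytometry-like events, and an
    end-to-end reproducible pipeline with CSV/JSON artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
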