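Package: ltbseg
Title: Simulated Psychophysics of Luminance Texture Boundary Segmentation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how luminance texture boundaries (regions that
    differ in their proportions of light and dark micropatterns) are segmented
    by image-computable observer models. Generates micropattern texture-disc
    stimuli and cosine-tapered luminance step edges, extracts diagonal
    luminance-difference and RMS-contrast features, implements signal-detection
    psychometric functions with a power-law transducer and lapse rate, one-stage
    luminance-difference models with optional divisive contrast normalization,
    and a two-stage filter-rectify-filter model built on ON/OFF
    difference-of-Gaussians channels. Includes maximum-likelihood fitting with
    grid-initialised local search, parametric bootstrap confidence intervals,
    Bayesian information criterion model comparison, adaptive 1-up-2-down
    staircase and constant-stimuli masking experiment simulators, and Pearson
    chi-squared condition-level statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
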