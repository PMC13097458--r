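Package: skinoverlap
Title: Quantifying Skin Colour Variation and Overlap in CIELAB Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying within-group variation and between-group
    overlap of human skin colour in the CIELAB colour space. Converts
    reflectance spectra or XYZ tristimulus values to CIELAB, summarises
    per-group colour moments and mean colour differences, and measures
    between-group overlap two ways: the fraction of samples whose minimal
    perceptual colour difference (Euclidean delta E) to another group falls
    below a perceptibility threshold, and the shared volume of voxelized
    colour gamuts refined by morphological criteria. Includes robust
    bootstrap summaries of overlap medians, a two-way ethnicity-by-gender
    ANOVA with effect sizes, a reproducible synthetic cohort generator for
    testing, and an end-to-end pipeline with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    car,
    stats,
    utils,
    tools,
    tibble,
    readr,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
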