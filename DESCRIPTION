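Package: lightboxr
Title: Quantifying Light-Absorbing Carbon Exposure from Lightbox Images of
    Passive Filter Samplers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a low-cost, passive method of estimating long-term
    indoor exposure to light-absorbing carbon (black and brown carbon).
    Passively exposed white filter surfaces darken with cumulative particle
    deposition; the change is quantified from multi-frame 12-bit grayscale
    lightbox photographs as a double-referenced change in mean pixel
    intensity (delta-PI) of a region of interest, normalised against an
    unexposed reference surface imaged in the same session. Includes
    darkening time-series analysis (interval rates, linear fits, lower
    limit of detection across a cohort, saturation detection via a
    replacement sampler), replicate-agreement statistics (Pearson and
    Spearman correlation, coefficient of variation, RMSE relative to the
    replicate mean, grouped agreement tables, among/within-location
    variability decomposition), and a synthetic lightbox simulator that
    generates whole imaging campaigns with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
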