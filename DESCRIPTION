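Package: bolusqc
Title: Quality Assessment of Contrast-Medium Bolus Time-Contrast Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the fidelity of contrast-medium boluses
    delivered by MRI power injectors from photometric time-contrast (TC)
    recordings. Fits a boxcar (piecewise-constant) model to each TC-curve by
    exhaustive least-squares changepoint search, computes the correlation
    with the fitted boxcar (cBCF) and the deviation of the effective from
    the programmed injection time (dBIT), and compares injector systems with
    Kruskal-Wallis tests, Dunnett-modified Tukey-Kramer pairwise comparisons
    with Bonferroni correction, analysis of covariance, and a
    contrast-medium compliance odds-ratio test. Includes a tanks-in-series
    injector simulator that generates synthetic recordings with pump-type
    specific flow profiles, tube-line dilution and photometric sensor noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    car,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
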