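Package: paddleire
Title: Dosimetry and Statistics for Irreversible Electroporation with
    Parallel Disc Paddles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing irreversible electroporation
    (IRE) of soft tissue compressed between two coaxial parallel disc
    electrodes ("paddles").  Computes the mid-plane current-density profile
    per ampere of delivered current semi-analytically via complete elliptic
    integrals, with an axisymmetric finite-volume Laplace solver as an
    independent numerical oracle; estimates the tissue necrosis
    current-density threshold per application site from recorded peak
    currents and histological lesion extents; implements the paired
    statistics used in small repeated-measures animal studies (exact
    McNemar test, one-way within-subject ANOVA, paired contrasts); and
    generates fully synthetic study-like cohorts with known ground truth
    for end-to-end validation of the estimation pipeline.
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
    Matrix,
    methods,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
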