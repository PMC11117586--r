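Package: gazewin
Title: Gaze-Contingent Moving-Window Analysis of Facial Expression Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis pipeline for gaze-contingent moving-window
    experiments on basic facial-expression recognition. Converts visual angles
    to on-screen pixels for aperture geometry, identifies fixations in raw
    60 Hz gaze logs with a dispersion-based (spatiotemporal) algorithm,
    computes judgment metrics (accuracy, confusion matrices, ordinal
    consensus and Shannon entropy on Likert confidence ratings), and runs the
    non-parametric group-comparison layer (Kruskal-Wallis with adjusted
    eta-squared, Dunn's post hoc with Bonferroni correction, paired Wilcoxon
    with rank-biserial effect size, and a-priori noncentral-F power
    analysis). Includes a seeded synthetic-data generator emulating the
    three visual-field conditions (no restriction, parafoveal+foveal 5
    degree aperture, foveal 2 degree aperture) so the full pipeline is
    testable without any experimental download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
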