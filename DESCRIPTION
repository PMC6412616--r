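Package: qube
Title: Quantitative Myocardial Blush Evaluation for Coronary Angiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies myocardial perfusion ("blush") on x-ray coronary
    angiogram runs. Implements the QuBE approach: contrast inversion,
    median-filter background estimation and subtraction, per-frame blush
    values from the brightest residual pixels inside a region of interest,
    integer panning correction, blush time-intensity curves, and the QuBE
    score (maximum rise plus maximum fall of the curve). Ships a synthetic
    angiogram simulator with known gamma-variate blush kinetics, vessel
    tree, diaphragm, catheter, cardiac motion and noise, plus the
    rank-based statistics (Spearman, Kruskal-Wallis, Lin's concordance,
    Wilcoxon signed-rank) used to study kernel-size and motion-correction
    effects on the score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
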