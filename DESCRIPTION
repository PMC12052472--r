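Package: eggscore
Title: Quantitative Surface Ornamentation Metrics for Eggshell Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying external eggshell ornamentation from
    triangular surface meshes. Standardized 10 mm surface sections are
    aligned, decimated to a fixed face budget and scored with three
    topographic metrics: Complexity (Dirichlet normal energy), Relief
    (mean face slope) and Orientation, a bounded -100..+100 score that
    contrasts surface area whose normals face along the egg's long axis
    with area facing around the short axis. Includes PLY/STL readers and
    writers, quadric edge-collapse decimation, a parametric generator of
    ornamented test surfaces, and the statistical comparison pipeline
    (asymmetric IQR outlier screening, exact two-sample
    Kolmogorov-Smirnov tests, bootstrap confidence intervals, Spearman
    rank correlation and harmonic-mean p-value meta-analysis) used to
    compare eggs within and between taxa.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
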