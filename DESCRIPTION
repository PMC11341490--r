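Package: canalmorph
Title: Monte Carlo Morphometry of the Femoral Medullary Canal
Version: 0.1.0
Authors@R:
    person("Canalmorph", "Developers", email = "maintainer@canalmorph.dev",
           role = c("aut", "cre"))
Description: Tools for morphological analysis of the femoral medullary cavity
    on transverse CT-like slice stacks. Extracts the cortical-bone and
    medullary-cavity regions per slice (Gaussian smoothing, low-cut
    thresholding, Canny edge detection, contour filling and subtraction),
    estimates region areas by uniform random point sampling with an exact
    pixel-traversal oracle, locates the isthmus and lesser-trochanter
    reference sections, and computes the classical canal flare indices
    (CFI, MCFI, DCFI, CI) together with per-slice area ratios and growth
    rates used in femoral stem prosthesis design. Includes a fully synthetic
    trumpet-shaped femur phantom with analytic ground truth, and
    method-agreement statistics (descriptives and one-way ANOVA) comparing
    the Monte Carlo estimates against exhaustive traversal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
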