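Package: odgrowth
Title: Growth Phenomics from Optical Density Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts raw optical-density time series of microbial cultures
    (Bioscreen-C exports or generic tab-delimited matrices) into calibrated
    population-size curves and extracts the three canonical fitness
    components: growth lag, population doubling time and growth efficiency.
    Curves are cleaned by a three-step filter chain (median, mean and
    monotonicity filters), blank-corrected and calibrated through the cubic
    response model y = x + c*x^3 that corrects the sublinear OD response at
    high cell densities.  Four per-curve quality indices score overall
    noisiness, local noisiness, spike counts and curve collapses, and flag
    low-quality curves against batch-derived percentile thresholds.  A
    synthetic-curve generator with known ground-truth traits and a
    configurable noise taxonomy (spikes, wide spikes, collapses,
    high-frequency noise, multimodal growth) supports benchmarking and
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), optparse, yaml, jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
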