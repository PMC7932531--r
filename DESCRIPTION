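Package: qsfoot
Title: Quantitative Statistical Framework for In-Shoe Plantar Pressure Offloading Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the offloading performance of custom-made
    insoles from in-shoe plantar pressure recordings during gait. Reads
    sensor-level pressure exports over irregular 99-sensor layouts, resamples
    them onto a regular 5 mm grid, segments walking records into stance
    phases, computes per-stance peak-pressure maps and the mean peak pressure
    map (MPPM), and determines statistically significant risk-regions of
    interest (R-ROIs) against the 200 kPa ulceration-risk threshold by
    cell-wise one-sample t-tests. Paired cell-wise tests map how an insole
    redistributes pressure relative to a flat-insole reference; group-level
    comparisons of per-foot R-ROI areas use Friedman and Wilcoxon signed-rank
    tests with Bonferroni correction. Includes noncentral-t and noncentral-F
    power calculators for step-count and cohort design, and a synthetic
    gait-pressure simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    readxl,
    igraph,
    pracma,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
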