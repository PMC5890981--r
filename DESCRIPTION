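Package: cagdrift
Title: Somatic CAG Repeat Expansion Analysis from Fragment Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies somatic CAG repeat expansion from capillary-electrophoresis
    fragment-analysis traces of the kind exported by GeneMapper. Converts fragment
    sizes (bp) to repeat numbers with an affine sizing calibration, calls repeat-unit
    peaks, builds normalized repeat-length distributions, normalizes each tissue
    against the same animal's germline (tail-at-weaning) baseline, pools per-group
    global distributions, and localizes treatment effects along the distribution with
    a quantile-cell comparison using F-test-gated Student/Welch t-tests and one-way
    ANOVA. Ships a synthetic electropherogram generator (stutter ladder, sizing
    jitter, intensity noise, tissue/age/treatment-dependent expansion drift) so the
    whole pipeline is testable end-to-end without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
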