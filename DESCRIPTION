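Package: bbgptest
Title: Beta-Binomial Gaussian Process Tests for Allele-Frequency Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks genomic features showing significant non-random temporal
    variation in high-throughput sequencing time series, with evolve-and-
    resequence (E&R) experiments as the primary use case. Read counts and
    sequencing depths are converted into per-observation allele-frequency
    posteriors under a conjugate beta-binomial model; the posterior means are
    then modelled with a Gaussian process whose noise covariance carries the
    per-observation beta-binomial variances, and each site is scored by the
    Bayes factor comparing a time-dependent (squared-exponential kernel)
    model against a time-independent (constant plus white noise) model.
    Includes the replicate-stratified Cochran-Mantel-Haenszel comparator
    test, a desk-scale Wright-Fisher pool-sequencing simulator, PoPoolation2
    sync-format input/output, and precision-recall ranking evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
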