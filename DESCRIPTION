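Package: methagree
Title: Agreement Analysis for Paired Genome-Wide DNA Methylation Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing agreement between repeated genome-wide DNA
    methylation measurements of the same subjects, for example beta-value
    matrices obtained with different DNA extraction methods on Infinium
    methylation arrays. Implements Bland-Altman analysis with a
    heteroscedastic variance function sigma(x) = exp(a + b*(x - 0.5)^2) fitted
    by maximum likelihood, binned distributions of per-site absolute mean
    differences, principal-component screening against technical covariates
    (Kruskal-Wallis and Spearman tests with Bonferroni correction), and
    global, per-CpG and regional paired differential-methylation testing with
    a sign-flip bootstrap family-wise error rate for candidate regions. A
    synthetic-data generator produces paired multi-method beta datasets with
    the statistical structure the analysis assumes, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
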