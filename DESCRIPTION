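Package: anchormaic
Title: Anchored Matching-Adjusted Indirect Comparison for Trial Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anchored matching-adjusted indirect comparison (MAIC)
    of two treatments studied in separate placebo-controlled trials, following
    the population-adjustment methodology of NICE DSU Technical Support
    Document 18. Individual patient data from one trial are reweighted by
    method-of-moments (exponential tilting) so that baseline means and
    proportions exactly match the aggregate baselines published for a
    comparator trial; weighted ANCOVA and weighted two-by-two effective-count
    models produce arm-versus-placebo contrasts, which are combined with the
    Bucher method into indirect mean differences and odds ratios with
    confidence intervals. Includes a paired-trial simulator with configurable
    covariate shift and effect modification for validating the pipeline,
    before/after balance tables with Wald, chi-square and Fisher tests,
    effective sample size diagnostics, forest plots, and a configuration-driven
    end-to-end pipeline runner.
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
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
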