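Package: bmprev
Title: Benchmark-Multiplier Estimation of Chronic Disease Prevalence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the prevalence of chronic diseases from imperfect,
    non-population-based data sources with the benchmark-multiplier method:
    a bias-corrected ratio estimator combining the known size of a
    well-enumerated disease subgroup (the benchmark) with that subgroup's
    share of the disease population (the multiplier), stratified Monte
    Carlo propagation of parameter uncertainty, coverage-based augmentation
    of under-covering benchmark registries with pseudo-records, descriptive
    comparison of candidate data sources, and a synthetic multi-source
    registry generator for end-to-end validation against a known truth.
    Includes a configuration-driven pipeline and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
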