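Package: glntrace
Title: Dual-Label 13C/15N Glutamine Tracer Accounting and Carbon Use
    Efficiency Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Isotope bookkeeping and carbon-use-efficiency (CUE) modelling
    for plants fed universally labelled L-glutamine (U-13C5,15N2-gln).
    Provides background correction of atom percent 13C/15N against matched
    unlabelled controls or natural abundance, molar excess-isotope contents,
    regression-slope conversions to the fraction of glutamine-derived carbon
    retained and the fraction of nitrogen acquired from glutamine, per-plant
    carbon and nitrogen budgets, estimation of organic versus inorganic
    nitrogen assimilation carbon costs by linearized least squares, a seeded
    forward mass-balance simulator of the dual-label feeding experiment, and
    a pipeline that runs the full analysis from tabular tissue measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
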