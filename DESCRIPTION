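Package: endoxtdm
Title: Cost-Effectiveness of Endoxifen Serum Monitoring in Adjuvant Tamoxifen Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Health-economic evaluation of therapeutic drug monitoring (TDM) of
    endoxifen, the active metabolite of tamoxifen, in women with ER-alpha
    positive breast cancer on adjuvant tamoxifen. Implements a three-state
    (disease-free, recurrent disease, death) partitioned-survival cohort model
    with lognormal survival extrapolation, hazard-ratio adjustment for adequate
    endoxifen exposure, age-specific background mortality, discounted costs and
    quality-adjusted life-years, one-way deterministic and probabilistic
    sensitivity analysis (cost-effectiveness plane, acceptability curves, net
    monetary benefit), parametric survival fitting and selection from published
    Kaplan-Meier summaries, and synthetic-data generators (parametric life
    tables, serum endoxifen cohorts, an individual-level microsimulation
    oracle) for all inputs the original study does not deposit.
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
    optparse,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
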