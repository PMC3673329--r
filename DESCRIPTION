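Package: moamatch
Title: Mode-of-Action Metabolite Pattern Matching for Preclinical Safety
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning repeat-dose rodent plasma metabolite profiles
    into toxicological safety signals. Implements matched-control fold
    changes and sex- and day-stratified Welch tests over a semi-quantitative
    metabolite panel, derivation of mode-of-action (MoA) metabolite
    signatures from reference compounds with hold-out validation,
    correlation-based pattern ranking and whole-profile comparison with
    percentile-calibrated, sex-specific match thresholds, and dose-stratified
    toxicity match tables with grand totals. A synthetic-study generator
    with planted MoA effects emulates the rat study design the method
    assumes, so the whole pipeline is testable without proprietary reference
    data.
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
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
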