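Package: combosyn
Title: Synergy Scoring for Multi-Drug Dose-Response Combination Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores synergy and antagonism of N-drug (N >= 2) dose-response
    combination screening data under four reference models (highest single
    agent, Bliss independence, Loewe additivity, and zero interaction
    potency), including four-parameter log-logistic curve fitting with LOESS
    and linear alternatives, leave-one-out matrix-completion outlier
    flagging, replicate statistics, sub-combination enumeration, synthetic
    fixture generation, static visual summaries, table export, and a
    command-line entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
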