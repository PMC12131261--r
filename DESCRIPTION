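Package: facebias
Title: Looking-Time Analysis of Facial Expression Processing in Macaques
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing preferential-looking and
    violation-of-expectation experiments on facial expression processing
    in rhesus macaques. Reads coded looking-event tables, applies trial
    inclusion criteria, computes per-trial attention-bias proportions and
    the population-level tests (one-sample t-tests against 0.5, linear
    mixed models with Satterthwaite degrees of freedom, Tukey-adjusted
    marginal-mean contrasts), predicts sixth-image looking times from the
    preceding sequence, builds per-subject composite facial-expression
    processing scores by trial-type z-standardisation, and fits the
    maternal-care and age mixed models on those scores. Ships a
    synthetic-data generator with configurable ground-truth effects so the
    whole pipeline can be exercised and calibrated without access to the
    original recordings. Includes a two-way random-effects intraclass
    correlation for inter-coder reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
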