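Package: marriagefitness
Title: Deterministic Fitness Model of Parental Conflict over Women's Marriage Age
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a deterministic life-history model of maternal and
    paternal lifetime reproductive fitness as a function of women's age at
    marriage, in a patrilocal low-income setting. Total fertility, low birth
    weight, child mortality, stunting, paternity uncertainty and (optionally)
    maternal mortality are all closed-form functions of marriage age. The
    package evaluates these quantities over marriage-age sweeps, encodes eight
    named intervention/shock scenarios as declarative parameter overrides,
    locates each parent's fitness-maximizing marriage age by grid search, and
    assembles the resulting parental-conflict table, with tidy tabular
    outputs, ggplot2 visualizations, CSV/JSON serialization and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
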