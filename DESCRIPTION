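Package: ylldecomp
Title: Decomposition of Changes in Years of Life Lost by Age Structure,
    Death Rate and Age at Death
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Compare the premature-mortality burden (years of life lost,
    YLL, expressed per 1000 population) between two populations or time
    points and decompose the change into three additive gradients:
    population age structure, overall death rate, and age at death.  Both
    a baseline-weighted (Laspeyres-like) and a comparison-weighted
    (Paasche-like) scheme are computed; their mean is a Fisher-style,
    residue-free decomposition whose components sum exactly to the total
    change.  Includes readers and writers for age-binned CSV tables and
    reference life tables, a synthetic scenario generator with known
    ground-truth gradients, JSON and CSV report writers, ggplot2-based
    plots, broom-style tidiers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
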