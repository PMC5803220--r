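Package: igpsim
Title: Molecular Gut-Content Analysis of Ladybird Predation and
    Intraguild Predation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for DNA-based gut-content analysis of
    aphidophagous predators. Fits binomial decay models of prey-DNA
    detectability in predator guts and derives half-detectability times
    (T50), applies detectability corrections to field predation
    proportions to rank predators net of digestion rate, compares
    predator species with binomial mixed models, and tests field-observed
    intraguild predation against expectations from laboratory bioassays
    with a two-part Monte Carlo simulation. Ships synthetic-data
    generators for feeding-trial, field-survey and laboratory bioassay
    datasets, plus small in-silico PCR utilities for diagnostic COI
    primers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
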