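Package: selectdeaths
Title: Selective Deaths, Reproductive Excess, and Speed Limits to Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for accounting the demographic cost of natural selection.
    Implements Haldane-style cost-of-selection calculators (selective deaths
    integrated over a sweep trajectory), speed limits to adaptation under
    finite reproductive excess (Haldane, Nei/Felsenstein, and extreme-value
    lead-based variants), a generalized life-history framework that computes
    per-transition reproductive excess and selective deaths for arbitrary
    ordered life cycles (including bottleneck generalizations for variable
    life cycles), the lead of an adapting asexual population in the
    multiple-mutations regime with its implied minimum reproductive excess
    and proportion of deaths that are selective, and an empirical pipeline
    that estimates the proportion of deaths that are selective from
    genotype-by-environment cohort survival tables, with an extreme-value
    (winner's curse) bias adjustment and a permutation gate on fecundity
    differences. A synthetic cohort generator emulates a 517-genotype,
    eight-environment Arabidopsis thaliana field design for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
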