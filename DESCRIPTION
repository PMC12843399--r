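Package: inquiryflow
Title: Multi-Level Process Mining of Simulation-Based Scientific Inquiry Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing process data from structured simulation-based
    scientific-inquiry tasks. Provides the Hydroelectric Power Plant task model
    (outcome table, safety constraint, dichotomous scoring), an agent-based
    simulator that generates raw interface event logs from parameterised
    first-order behavioral profiles, a two-level behavior coding scheme
    (micro interface actions and macro inquiry phases), performance subgrouping
    by task effectiveness and Gaussian-mixture efficiency profiles, macro-level
    analytics (offset Poisson rate models with HC3 robust intervals, state
    distribution plots, gap-tolerant frequent-subsequence mining with Wilson
    intervals and FDR-adjusted two-proportion tests), and micro-level analytics
    (normalised Shannon entropy, Dirichlet-multinomial smoothed first-order
    transition models, and bootstrap delta probability maps). All stages run
    end-to-end from a single seeded pipeline so analyses are reproducible
    without access to classroom data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
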