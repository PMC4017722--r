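Package: qsarfuse
Title: Combinatorial Fusion of QSAR Prediction Systems for Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining multiple quantitative structure-activity
    relationship (QSAR) prediction systems by combinatorial fusion. Provides
    diversity rank/score functions and graphs for pairs of scoring systems,
    exhaustive enumeration and evaluation of all score combinations against
    experimental IC50 activities, selection heuristics for accurate and
    diverse systems, training/testing split validation, and the downstream
    virtual-screening triage filters (estimated-activity and docking-energy
    cutoffs, top-k reporting). Includes a seeded synthetic-data generator of
    correlated noisy prediction systems for testing every stage, packaged
    checkpoint kinase 2 (Chk2) inhibitor study tables, a pipeline runner, and
    ggplot2 visualisations of rank/score graphs and combination leaderboards.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
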