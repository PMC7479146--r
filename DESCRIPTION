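Package: ringlife
Title: Growth-Lifespan Trade-Offs and Data-Driven Forest Demography from Tree Rings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to estimate growth-lifespan trade-offs from tree-ring data and to
    propagate them through a stochastic cohort forest simulator. Reads and writes
    Tucson (RWL) and long-form CSV ring-width data, merges duplicate cores, derives
    per-tree early growth and age summaries, and applies site- and species-level
    screening rules. Trade-offs are estimated by exponential quantile regression
    (95th-quantile age versus mean early ring width) with an exact pinball-loss
    solver, with companion diagnostics for sample-size and big-tree sampling biases.
    Size- and age-dependent mortality is inferred from steady-state stand diameter
    distributions and fitted to parametric hazard models. A 600-year annually seeded
    cohort simulator with an age-modulated warming growth stimulus quantifies how
    growth stimulation transiently raises, then neutralizes, standing basal-area
    stocks. A synthetic-data generator with known trade-off, noise and mortality
    structure supports end-to-end testing without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
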