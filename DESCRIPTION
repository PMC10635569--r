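Package: bfgem
Title: Constraint-Based Modeling of Gut Bacterial Fermentation Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating genome-scale metabolic
    models of fermentative gut bacteria such as Bacteroides fragilis.
    Provides model input/output in SBML Level 3 FBC, COBRA JSON, and a
    documented tabular dialect; a flux balance analysis engine with flux
    variability analysis, blocked-reaction and dead-end detection, and
    single-gene deletion; assembly of biomass objective functions from
    macromolecular composition tables with carrier-molecule cycling and
    mass normalization; fitting of growth- and non-growth-associated ATP
    maintenance coefficients against observed growth rates; greedy
    component-driven gap filling from a universal reaction pool; and the
    downstream analysis workflows (nutrient utilization screening,
    fermentation product envelopes, carbon balancing, growth efficiency,
    and co-metabolism / differential gene essentiality). Includes seeded
    generators for synthetic toy networks with hand-computable optima so
    every component is testable without external model files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    xml2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
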