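Package: treeflux
Title: Whole-Tree Chamber Gas Exchange, Carbon Budgets, and Dendrometer
    Growth Under Drought and Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for continuous whole-tree gas-exchange
    chamber experiments on drought and recovery. Converts paired
    reference/sample airstream records into compartment CO2 and H2O
    fluxes with water-dilution and blank-chamber background corrections,
    derives leaf-area normalized gas exchange (net assimilation,
    transpiration, stomatal conductance, intrinsic water-use
    efficiency), integrates daily and cumulative whole-plant carbon
    budgets, extracts stem growth and tree water deficit from point
    dendrometer traces under the zero-growth assumption, tracks Huber
    values (sapwood:leaf area), and produces treatment-level summaries.
    Includes a synthetic scenario generator that emulates the
    statistical structure of multi-tree drought-recovery chamber studies
    with retained ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
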