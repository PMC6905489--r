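Package: c4flux
Title: Constraint-Based Modelling of C3 to C4 Leaf Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to curate a compartmented one-cell C3 leaf metabolic model,
    compose a two-cell mesophyll/bundle-sheath model with a dual Rubisco
    population, and run the parsimonious flux balance analysis (pFBA) and flux
    variability analysis (FVA) experiments that probe the emergence of the C4
    carbon-concentrating cycle: photorespiration scans, decarboxylation-enzyme
    knockouts, light amount/distribution grids, nutrient-limitation scans, and
    intercellular transport-ratio scans. Linear programs are solved through a
    bundled interface to the GNU Linear Programming Kit (GLPK). Models are read
    and written as SBML Level 3 with the Flux Balance Constraints package, and
    a deterministic reduced leaf-network generator provides a fully
    carbon/nitrogen-balanced fixture so every analysis stage runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: GNU GLPK library (libglpk)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    knitr,
    rmarkdown,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
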