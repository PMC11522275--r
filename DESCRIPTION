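Package: asebio
Title: Ecosystem-Service Potential Mapping, Stakeholder Weighting and the ASEBIO Composite Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-temporal ecosystem-service (ES) assessment on categorical
    land-cover grids: min-max normalization of ES potential layers, a percent temporal
    change index with standard-deviation based classification, Analytic Hierarchy
    Process (AHP) stakeholder weighting with consistency ratios, the ASEBIO composite
    weighted-overlay index, land-cover capacity-matrix perception mapping, and
    model-versus-stakeholder agreement statistics (Pearson correlation matrices,
    paired t-tests, one-way ANOVA). Includes a seeded synthetic-landscape generator
    (CORINE-like land cover, class-conditional ES layers, multi-stakeholder score
    tables, contiguous zones) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
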