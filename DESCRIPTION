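Package: acsroutes
Title: Street-Network Exposures and Active School Commuting Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: GIS-style analysis of active commuting to school (ACS) on a
    street network: network-distance school catchment buffers with resident
    density, intersection density and a mixed-use entropy index; home-school
    route measures (network distance and pedestrian route directness, PRD);
    binary logistic exposure-outcome models with collinearity and confounding
    diagnostics; ROC/Youden cut-point analysis of route measures; and
    cross-tabulation of commuting status by PRD ranges. Includes a synthetic
    city generator with a known logistic behaviour model so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    withr,
    knitr
Config/testthat/edition: 3
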