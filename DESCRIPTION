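Package: bedcarbon
Title: Riverbed Sediment Diagenesis and Carbon Resuspension Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates benthic carbon cycling in stream networks: a two-layer
    (aerobic/anaerobic) sediment diagenesis model with labile, slow-reacting
    and non-reacting organic carbon pools, methanogenesis with saturation
    bubbling, methane oxidation and diffusion, burial, and storm-driven
    carbon resuspension, coupled to a single well-mixed reach that routes
    suspended sediment and particulate/dissolved organic carbon from upland
    loads to the watershed outlet. Includes watershed-normalized annual
    budget accounting, Nash-Sutcliffe and percent-bias model evaluation,
    Latin-hypercube global sensitivity analysis by multiple regression, and
    a seeded storm-pulse synthetic forcing generator so the full pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
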