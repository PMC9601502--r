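Package: ddpcrquant
Title: Droplet Digital PCR Quantification of Meat Species Adulteration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calibration-curve-free quantification of adulterant meat species
    (pork, chicken) in beef from droplet digital PCR (ddPCR) data. Converts
    raw droplet counts to absolute copy-number concentrations via Poisson
    partition statistics, calibrates a transfer coefficient K that maps
    copy-number ratios of single-copy nuclear genes to mass ratios, turns
    copy ratios of unknown samples into adulterant mass fractions, and
    implements the assay-validation battery (linearity, limit of detection,
    limit of quantification, repeatability and reproducibility). A droplet
    partition simulator with Poisson occupancy and lognormal replicate noise
    makes every stage testable without laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
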