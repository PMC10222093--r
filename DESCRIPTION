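Package: larkin
Title: Release-Kinetics Modelling and Exposure Projection for Long-Acting Implants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits closed-form drug-release kinetics models (zero-order,
    first-order, second-order, Higuchi, Korsmeyer-Peppas, Hixson-Crowell,
    Weibull, biexponential, Peppas-Sahlin, Population Council) to ex vivo
    residual-drug and label release-rate data from long-acting subcutaneous
    implants, selects among them by adjusted R-squared, converts the winning
    exponential families into releasable-fraction-corrected implant input
    functions, and drives a reduced subcutaneous-depot plus one-compartment
    disposition model to project multi-year plasma exposure with lognormal
    inter-individual variability. Includes a seeded synthetic-data generator
    emulating device-removal study designs so the full analysis pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
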