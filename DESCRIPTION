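Package: fieldqsar
Title: Field-Based 3D-QSAR Modelling with PLS, External Validation and
    Applicability-Domain Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds comparative molecular field (CoMFA-style Lennard-Jones and
    Coulomb probe energies) and molecular similarity (CoMSIA-style Gaussian
    similarity indices) descriptors on a rectilinear lattice around
    pre-aligned small-molecule series, fits partial least squares regression
    models with leave-one-out cross-validation, searches field combinations,
    and validates models with the Golbraikh-Tropsha external test battery,
    Roy's r2m metric, Y-randomization and a standardization-based
    applicability domain.  Includes activity arithmetic (pIC50, selectivity
    index), Lipinski/Veber druglikeness screening, contour-map extraction and
    a synthetic congeneric-series generator with a planted field-activity
    relationship for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
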