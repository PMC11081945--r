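Package: fdhemo
Title: Flow-Diverter Sizing and Intra-Aneurysmal Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for studying how the size discrepancy between
    a braided flow diverter and its parent artery changes metal coverage rate,
    pore density, and intra-aneurysmal hemodynamics. Builds parametric
    sidewall-aneurysm geometries, models ideal braided-stent deployment and
    compaction, homogenizes the deployed braid into a permeable neck screen,
    and runs a 2D pulsatile incompressible Navier-Stokes solver (staggered-grid
    projection method, Womersley-type inlet) to compute inflow rate, average
    sac velocity, energy loss, wall shear stress, TAWSS and OSI, together with
    their reduction rates between unstented and stented runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
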