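Package: rifpbpk
Title: Whole-Body PBPK Drug-Disease Models for Single-Dose Rifampicin
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An open re-implementation of a whole-body, perfusion-limited
    physiologically based pharmacokinetic (PBPK) model of single-dose
    rifampicin in healthy adults and in tuberculosis and liver-cirrhosis
    (Child-Pugh A-C) populations. Provides seeded virtual-population
    generation with disease pathophysiology (hypoalbuminemia, reduced liver
    volume, hepatic enzyme abundance and organ blood flows),
    Rodgers-Rowland tissue:plasma partitioning and Vss prediction for an
    ampholyte, retrograde well-stirred hepatic clearance, first-order oral
    absorption derived from effective jejunal permeability, a stiff-safe
    ODE simulation engine, non-compartmental analysis, and fold-error model
    evaluation (observed/predicted ratios, AFE, RMSE, two-fold criterion)
    against packaged observed/predicted parameter tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
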