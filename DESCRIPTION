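Package: transportddi
Title: Transporter-Mediated Drug-Drug Interaction Prediction from In
    Vitro Uptake, Inhibition and Permeability Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An in-vitro-to-in-vivo pipeline for renal and intestinal
    transporter drug-drug interaction (DDI) assessment. Converts raw
    radiolabelled uptake-assay plate data into protein-normalised,
    vector-control-corrected uptake activities; fits Michaelis-Menten
    kinetics (Km, Vmax) and four- or five-parameter logistic inhibition
    curves (IC50, converted to Ki by Cheng-Prusoff); computes bidirectional
    Caco-2 apparent permeability with lucifer-yellow integrity gating; and
    feeds unbound Cmax, intestinal [I2] and fraction-excreted values into a
    mechanistic static model of victim-drug AUC change under OCT and MATE
    transporter inhibition. Includes a plate-level synthetic-data simulator
    with known ground truth for end-to-end validation of every fitting
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
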