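Package: co2screen
Title: Screening Carbanion Nucleophiles for Stable CO2 Carboxylation Adducts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the thermodynamic stability of base-mediated C-H
    carboxylation adducts. From SMILES strings of carbon-centered
    nucleophiles (carbanions with a CA site flanked by two carbon
    neighbors), the package generates conformer ensembles, computes
    steric and electronic descriptors (buried Sterimol B1 at the
    carbanionic site, HOMO energy, Hirshfeld site-dipole magnitude)
    aggregated over Boltzmann-weighted ensembles, screens candidates by
    a HOMO-energy threshold, and predicts CO2 affinity (the negative
    Gibbs free reaction energy of CO2 addition, kcal/mol) with a
    three-parameter multivariate linear regression model. Includes an
    electronic-structure backend contract with a deterministic mock, an
    engine-output parser, model selection by exhaustive subset search
    with cross-validation, an end-to-end screening pipeline with
    caching and reports, and synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
SystemRequirements: python (>= 3.8) with rdkit, on PATH
Imports:
    ChemmineR,
    ggplot2,
    jsonlite,
    optparse,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
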