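Package: agrimacc
Title: Agricultural Carbon Sequestration Options and Marginal Abatement
    Cost Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale economic assessment of carbon dioxide sequestration
    options on agricultural land: enhanced soil organic carbon management on
    cropland and pastures, biochar application, and silvo-pasture systems.
    Provides a synthetic world generator, a monthly light-use-efficiency stand
    growth simulator for silvo-pasture tree strips, vintage-tracked saturating
    carbon-flux accounting, a crop-residue and biochar feedstock chain with
    merit-order competition, profit-maximising technology adoption under
    linearly increasing greenhouse-gas price trajectories with quadratic
    adoption-cost calibration, marginal abatement cost curve extraction, and an
    ex-post farmer/government economics ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
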