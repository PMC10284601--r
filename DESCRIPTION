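Package: hemox
Title: Hemoglobin Oxygen-Equilibrium, Allosteric-Effector and Thermal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hemoglobin oxygen-equilibrium (tonometry)
    experiments: Hill-plot estimation of P50 and the cooperativity coefficient
    n50 with delta-method standard errors, pH standardization of log P50 by
    linear regression, Bohr-coefficient estimation, quantification of
    2,3-diphosphoglycerate and chloride effector effects, van't Hoff apparent
    enthalpy of oxygenation with the oxygen-solubilization correction, and
    ammonium-sulfate salting-out solubility curves. Includes a two-state
    (Monod-Wyman-Changeux) allosteric forward simulator with oxygenation-linked
    proton, chloride and organophosphate binding and per-equilibrium
    enthalpies, so every pipeline stage is verifiable by parameter recovery on
    synthetic data that emulate the thin-film measurement protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
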