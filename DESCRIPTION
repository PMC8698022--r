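Package: scsolub
Title: Solid Solubility in Supercritical Carbon Dioxide by Cubic Equations of State
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermodynamic modeling of solid drug solubility in supercritical
    carbon dioxide with cubic equations of state (Redlich-Kwong,
    Soave-Redlich-Kwong, Peng-Robinson). Implements the compressed-gas
    solubility model with Poynting correction, classical van der Waals and
    Lorentz-Berthelot mixing rules, the Schmitt-Reid infinite-dilution
    modification of the Peng-Robinson equation, AARD-objective parameter
    regression (binary interaction parameter, per-isotherm sublimation
    pressure, or solute attraction and covolume parameters), Clausius-Clapeyron
    sublimation-pressure representation and enthalpy extraction, and the
    density-based Mendez-Santiago-Teja and Bartle correlations used for data
    consistency checking and sublimation-pressure estimation. Ships a
    forward-model synthetic-data generator emulating penicillin-class
    solubility isotherms for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
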