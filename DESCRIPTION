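Package: csfext
Title: Extended Combined Severity Factor Modeling of Organosolv Fractionation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Phenomenological modeling of formic acid fractionation of
    lignocellulosic biomass through an extended combined severity factor
    (CSF_ext) that folds temperature, reaction time and solvent concentration
    into a single severity ordinate. Provides the classical severity factor
    (log R0) and combined severity factor, Arrhenius- and Logistic-based
    solubilization models mapping CSF_ext to the degree of component
    solubilization, joint estimation of severity constants and model
    parameters by linearized multiple regression with a direct nonlinear
    least-squares cross-check, mass-balance derivation of solubilization
    fractions from solid yield and composition data, and a seeded synthetic
    data generator for end-to-end parameter-recovery studies. Ships the
    16-run orthogonal fractionation design of sugarcane bagasse as a
    plain-text fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
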