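Package: aggrekit
Title: Amyloid Aggregation Kinetics, Binding Thermodynamics and Particle
    Sizing Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of amyloid (amylin/hIAPP) aggregation
    inhibition assays. Fits the two-step autocatalytic
    nucleation-elongation model to thioflavin T fluorescence traces and
    derives nucleation and elongation rate constants and characteristic
    times; analyses intrinsic-fluorescence quenching titrations
    (Stern-Volmer, double-logarithmic binding plot, quenching-mechanism
    classification) and Van't Hoff binding thermodynamics; computes
    endpoint percent inhibition and four-parameter log-logistic IC50
    dose-response fits; sizes particles from dynamic light scattering by
    second-order cumulant analysis and the Stokes-Einstein relation.
    Includes seedable synthetic-data generators emulating each assay so
    every analysis stage is testable end to end, plus validated CSV
    readers, writers and a consolidated report builder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
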