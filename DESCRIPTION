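Package: hdxladder
Title: Deuterium Isotope Ladders from Microdroplet Hydrogen-Deuterium
    Exchange Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of deuterium isotope ladders produced by
    microdroplet hydrogen-deuterium exchange (HDX) ambient ionization mass
    spectrometry of small molecules. Provides exact-mass and natural isotope
    pattern computation from chemical formulas, a Poisson-binomial forward
    model of per-site exchange with charge-site deuteron and back exchange,
    ladder detection in centroided spectra with natural-isotope correction,
    discrimination of isobaric ions by exchangeable-site counts and base-peak
    shifts, two-component isobaric mixture deconvolution by an L1
    pattern-matching loss, internal-standard calibration for absolute
    quantitation of one isobar, and deuterium-feature-augmented PCA profiling
    of case/control cohorts, together with seeded synthetic-data generators
    for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    mzR
Config/testthat/edition: 3
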