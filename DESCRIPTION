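Package: mlcHIA
Title: Micellar Liquid Chromatography Retention Modelling and Prediction of
    Human Intestinal Absorption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for micellar liquid chromatography (MLC) with a
    biomimetic bile-salt/lecithin mobile phase. Converts chromatograms or
    retention-time tables into retention factors, fits the reciprocal
    retention-factor versus micellar-concentration line to obtain
    micelle-water partition coefficients (log Pmw), and fits a logit-linear
    multiple regression of percentage human intestinal absorption (%HIA) on
    log Pmw and polar surface area, with PRESS-based predictive R-squared,
    backward elimination under variance-inflation screening, and validation
    reporting. Includes mixed-micellar-system arithmetic (mixture CMC,
    micellar concentration, dilution design), seeded simulators for
    chromatograms, retention tables and compound tables with known ground
    truth, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
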