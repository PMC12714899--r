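Package: tgtkit
Title: Quantification of Thermal Gradient Test Behavior in Rodents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the linear thermal gradient test (TGT), a
    behavioral assay in which a rodent roams a corridor spanning a 4-58 degree
    Celsius floor gradient and its position distribution reports thermal
    preference and avoidance. Converts center-of-mass tracking tables into
    zone-occupancy profiles, fits the Gaussian temperature-preference model
    (most preferred temperature T_peak, distribution width SD, peak occupancy),
    compares groups with the extra sum-of-squares F test on nested fits,
    computes locomotion and immobility-bout metrics, and plans sample sizes
    from Cohen's d with a pooled residual standard deviation. Includes a
    seeded Ornstein-Uhlenbeck thermotaxis simulator whose stationary law is
    the Gaussian occupancy the assay fits, so every stage of the pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
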