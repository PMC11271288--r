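Package: arcmegan
Title: Arctic Updates to the MEGANv2.1 Isoprene Temperature Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models isoprene emission from high-latitude ecosystems with the
    MEGANv2.1 activity-factor framework and Arctic-specific updates: a sedge
    (Carex, Eriophorum) short-term temperature response with an activation
    energy and emission factor that acclimate to the 10-day mean air
    temperature, and a willow (Salix) emission capacity that acclimates to
    the previous-day mean. Provides Arrhenius and Q10 fitting of leaf-chamber
    temperature-ramp experiments, lag-correlation screening of temperature
    history, site-level flux modelling as a plant-functional-type mixture
    with bounded least-squares cover-fraction fitting against
    eddy-covariance observations, annual-emission trend estimation with a
    Mann-Kendall test, and seeded synthetic-data generators for chamber and
    site records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
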