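Package: floodpalm
Title: Oil Palm Suitability and Economics in Tropical Floodplain Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing oil-palm land suitability and plantation
    economics in tropical floodplain landscapes. Provides a seeded synthetic
    floodplain landscape generator (elevation, distance to river, soil
    suitability, land titles, palm productivity at 1-ha resolution), a
    25-year palm-capacity-scaled discounted cash-flow model with cost
    calibration, discount-rate sensitivity and break-even analysis, decision-
    rule and CART classifiers for flood-driven suitability mapping with
    10-fold cross-validated pruning, error-matrix accuracy assessment
    (overall accuracy and Cohen's kappa), and categorical area
    cross-tabulation for land-title and forest-system accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rpart,
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
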