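Package: cattletype
Title: Production-Type Classification of Cattle Farms from Linked Registry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies cattle farms into five production types (calf
    fattening, dairy, cattle fattening, rearing, suckler cow) from
    animal-movement, milk-test and antibiotic-prescription registries.
    Provides an event-level synthetic registry simulator for the five
    production types, eligibility filtering and extraction of 24 farm-year
    features based on animal-day accounting, grouped cross-validated
    training of random-forest, support-vector-machine and neural-network
    classifiers, bootstrap-based evaluation, Shapley-value feature
    attribution, and probability calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lubridate,
    ranger,
    e1071,
    nnet,
    yaml,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
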