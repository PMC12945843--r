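Package: hspscreen
Title: Hansen Solubility Parameter and Flory-Huggins Miscibility Screening
    for Amorphous Drug Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predictive preformulation toolkit for amorphous solid
    dispersions, mesoporous silica systems and co-amorphous formulations.
    Estimates Hansen solubility parameters and molar volume from
    functional-group counts (Hoftyzer-Van Krevelen and Fedors group
    contributions), computes the Hansen interaction radius (Ra) and the
    Flory-Huggins interaction parameter (chi) for drug-excipient pairs,
    classifies pairs against standard miscibility thresholds, ranks
    candidate stabilisers, and checks formulation stoichiometry (percent
    yield, HPLC drug content, equimolar component masses and w/w drug
    loading). Ships a reference data set for cefdinir and seven candidate
    stabilisers together with a synthetic-substance generator so every
    stage can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    ChemmineR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
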