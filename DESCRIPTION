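Package: lomaspulse
Title: Plant Community Dynamics of Fog-Oasis (Lomas) Vegetation Surveys
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for repeated vegetation-survey data from
    fog-oasis (lomas) ecosystems: plot- and landscape-level diversity
    metrics (Shannon alpha and gamma, richness, density, cover), an
    importance value index, a wet/dry seasonality index with stabilization
    detection, Spearman climate-association screens with Bonferroni
    correction, all-pairs paired t-tests between campaigns, Kruskal-Wallis
    tests across tourist-use zones, and a from-scratch detrended
    correspondence analysis with rare-species downweighting. Includes a
    synthetic survey generator with known ground truth so every stage is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
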