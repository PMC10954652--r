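Package: habitatshift
Title: Land-Cover Change and Monarch Butterfly Habitat Resource Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for translating land-use/land-cover (LULC) change into
    changes in migratory habitat resources for the eastern monarch butterfly
    (Danaus plexippus) across Mexico and Texas. Computes class-to-class
    transition matrices and gain/loss/net/gross change statistics from paired
    categorical landscapes or area tables, with per-zone (county/municipality)
    summaries; builds per-class seasonal resource distributions for nectar
    scores and milkweed densities from expert-elicitation surveys,
    classification-scheme agreement matrices (crosswalks), crop-composition
    weighting, and zero-inflated count-model fits to field plot data;
    propagates land-cover change into resource change by Monte Carlo
    simulation with an analytic-expectation oracle, zonal change maps, and
    cross-region z-score rescaling; and fits ordinary least squares trends to
    seasonal median-composite climate and NDVI series. A synthetic-data
    module generates all pipeline inputs with known ground truth so every
    stage can be exercised without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    fitdistrplus,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
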