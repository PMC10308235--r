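Package: quakebiogeo
Title: Isotope Biogeochemistry and Bioenergetics of Post-Earthquake Subseafloor Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for the geochemical analyses used to
    interpret earthquake-associated subseafloor core samples: stable-isotope
    fractionation algebra and equilibrium calibrations for the H2-H2O and
    CH4-H2O systems, Keeling-plot endmember regression for headspace H2,
    kinetic fractionation-factor fitting for low-temperature Fe-H2O batch
    experiments, multiple-sulfur-isotope statistics (capital-delta-33S,
    epsilon-34, lambda-33) with mass-balance mixing curves, sulfate-traced
    seawater-contamination correction of pore-water depth profiles, catabolic
    Gibbs free-energy landscapes for competing hydrogenotrophic metabolisms
    under B-dot activity and weak-acid speciation models, and population
    density estimation from endpoint dilution cultivation and microscopy
    counts. A seeded synthetic-data module emulates the structure of
    expedition core data so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
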