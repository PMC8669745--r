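Package: soilenzkin
Title: Depth-Resolved Soil Exoenzyme Kinetics and Temperature Sensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reduces fluorometric microplate assays of soil extracellular
    hydrolases (beta-glucosidase, leucine aminopeptidase, acid phosphatase)
    to quench-corrected activity rates per gram dry soil, applies replicate
    quality control, fits two-parameter Michaelis-Menten models with a
    transform-both-sides Box-Cox correction for heteroscedastic analytical
    variance, derives kinetic traits on dry-soil and microbial-biomass-carbon
    bases, and estimates temperature sensitivity with Q10/Arrhenius and
    Macromolecular Rate Theory models compared by information criteria.
    Includes factorial ANOVA with Tukey compact letter displays, percent
    decline summaries across a soil depth profile, and a synthetic campaign
    generator emulating a full factorial depth-by-temperature assay design so
    every pipeline stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
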