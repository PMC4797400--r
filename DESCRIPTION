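Package: mousedose
Title: Preclinical Lu-177 Radioimmunotherapy Dosimetry and Therapy Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for internal radionuclide dosimetry of a
    Lu-177-labelled antibody in mouse prostate-cancer xenografts.
    Fits bi-exponential time-activity curves and computes cumulated
    activities per source region, builds a parameterised voxel mouse
    phantom, estimates S-factors by Monte Carlo particle transport with
    simplified beta and photon physics, combines them into MIRD organ
    mean absorbed doses, inverts a bone-marrow dose limit into an
    administered-activity prescription, and summarises therapy efficacy
    (caliper tumour volumes, humane endpoints, Kaplan-Meier survival).
    A synthetic-data generator emulates the biodistribution and therapy
    cohorts so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
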