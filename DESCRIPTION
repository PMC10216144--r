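Package: clmsi
Title: Cardiolipin Profiling from Mass Spectrometry Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Enumeration and exact-mass annotation of doubly deprotonated
    cardiolipin (CL) and monolysocardiolipin (MLCL) species in negative-ion
    mass spectrometry imaging data, with a synthetic DESI-FAIMS-like data
    generator for validation. Provides elemental-formula arithmetic, isotope
    envelopes and charge-state inference from isotopologue spacing, profile-
    mode peak picking and ppm matching, MS2 acyl-chain assignment, CID/UVPD
    double-bond isomer ratio computation, region-of-interest signal-to-noise
    extraction from continuous-mode imzML images, chain-length ratio
    statistics, log-transformed centered PCA with per-species loading
    contributions, and Holm-adjusted nonparametric group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
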