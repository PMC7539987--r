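Package: xanthoq
Title: Xanthophyll-Cycle Kinetics and Photoprotective Quenching Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic simulation and analysis of xanthophyll-cycle driven
    photoprotection in green algae and plants. Provides an ODE model of
    violaxanthin de-epoxidation (in vitro enzyme assays and in vivo
    light-driven operation) coupled to a non-photochemical quenching (NPQ)
    model with qE, qZ and qI components; quantification of HPLC pigment
    chromatograms and the de-epoxidation index; saturating-pulse PAM
    fluorometry processing (NPQ kinetics, Fv/Fm, qE vs slowly relaxing
    quenching); Gaussian deconvolution of 77 K emission spectra with
    internal-standard normalization and photosystem-specific quenching
    statistics; instrument-response-convolved multi-exponential fitting of
    time-resolved fluorescence decays; asymptotic-exponential correlation of
    de-epoxidation with NPQ components; and seeded synthetic-data generators
    for every instrument modality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
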