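Package: peristroma
Title: Spatial Dissection of Stroma-Mediated Drug Resistance in Tumor Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying and simulating environment-mediated drug
    resistance (EMDR) conferred by tumor stroma. Infers net growth,
    proliferation and death rates from tumor volume time series and BrdU
    labeling indices; computes radial distribution functions of
    marker-positive tumor cells relative to pixelated stroma with
    label-shuffle complete-spatial-randomness envelopes; runs an on-lattice
    agent-based model of tumor cells under baseline growth and targeted
    therapy with a peristromal protection niche; and performs in silico
    perturbation experiments (EMDR magnitude, distance, producer fraction,
    stroma abundance and dispersal) that quantify residual disease.
    Includes synthetic-tissue generators with controlled stroma abundance
    and dispersal for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
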