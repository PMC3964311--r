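Package: reporternoise
Title: Intrinsic and Extrinsic Noise Decomposition for Two-Reporter Gene
    Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing gene-expression noise in synthetic
    mammalian transgenes measured by two-colour flow cytometry. Implements
    an alpha-calibrated extension of the classical two-reporter assay that
    decomposes total noise into intrinsic and extrinsic components when the
    two reporters are not identically regulated, the stated cytometry
    preprocessing (scatter gating, positive gating against an uninduced
    control, standard-deviation trimming), a stochastic steady-state
    simulator of negative-autoregulation and simple-negative-regulation
    circuits driven by Dox/rtTA activation and LacI/IPTG repression, and
    efficiency-corrected delta-delta-Ct copy-number estimation from qPCR
    dilution curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    grDevices,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
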