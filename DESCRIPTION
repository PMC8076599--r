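Package: oometab
Title: Single-Cell GC-MS Substrate Profiling of Membrane Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for substrate profiling of
    heterologously expressed membrane transporters in Xenopus laevis oocytes
    by GC-MS metabolomics. Generates synthetic transport experiments
    (symport, antiport, uniport) with endogenous metabolic drift, renders
    them as GC-MS batches with an n-alkane retention-index ladder and a
    ribitol internal standard, and analyses them through peak detection and
    deconvolution, Kovats retention-index calibration, tiered
    spectral-library identification with qualifier-ion validation, batch
    quality control, absolute quantification against grouped amino-acid
    standards, and the dual fold-change / absolute-difference statistics
    used to call transporter substrates and exchanger efflux/influx
    substrates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
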