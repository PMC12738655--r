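Package: alphacell
Title: Single-Cell Dosimetry and DNA Damage Simulation for Targeted
    Alpha Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale Monte-Carlo simulator of subcellular dosimetry for
    alpha-emitting radionuclides used in targeted alpha therapy (Ac-225,
    Ra-223, Pb-212, At-211).  Samples full radioactive decay chains or
    discrete alpha spectra, transports alpha particles along straight
    tracks through a two-sphere cell model using continuous-slowing-down
    stopping-power tables for liquid water, scores absorbed dose to the
    nucleus and nucleus-surface crossings per parent decay, and estimates
    DNA damage (single-strand breaks, simple and complex double-strand
    breaks) by density-based clustering of ionization events.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
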