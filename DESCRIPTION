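Package: tdfret
Title: Time-Domain Transition Metal Ion FRET Analysis of TCSPC Lifetime Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulate and fit time-correlated single photon counting (TCSPC)
    fluorescence decay histograms with a reconvolution FRET model in which
    donor-acceptor distances follow one or two Gaussian distributions,
    including a two-acceptor extension for intersubunit FRET in homomeric
    proteins.  Fitted state occupancies are converted into conformational
    free energies (delta G, delta delta G) via the Boltzmann relation and
    ligand dose-response relations are fit with a quadratic tight-binding
    model.  Includes Poisson-weighted chi-square single and global fitting,
    chi-square profile and surface identifiability diagnostics, a
    ground-truth synthetic data generator, delimited-text histogram I/O and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
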