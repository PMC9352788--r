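Package: mvitc
Title: Multivalent Binding Kinetics from Isothermal Titration Calorimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits integrated isothermal titration calorimetry (ITC) heats with
    the classical Wiseman 1:1 isotherm and with a multivalent extension in
    which the association constant varies per injection: microscopic on/off
    rates of an s-valent ligand-receptor binding define a transition-rate
    matrix that is coarse grained by PCCA+ spectral clustering to a two-state
    (bound/unbound) macro model at each free-ligand concentration. Includes
    concentration bookkeeping for the titration schedule, quintic-spline
    integration of power traces, timescale-separation diagnostics,
    perturbation-based robustness checks, and forward simulators that
    generate synthetic heats and power traces with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
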