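Package: tatabend
Title: Single-Molecule FRET Analysis of TBP-Induced Promoter DNA Bending
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule FRET studies of
    promoter DNA bending by the TATA-binding protein (TBP) and
    transcription factor B. Implements confocal ALEX burst analysis
    (sliding-window burst search, background and crosstalk correction,
    proximity ratio E and stoichiometry S, ALEX-2CDE/FRET-2CDE kernel
    filters, Gaussian population fits of E histograms), hidden-Markov
    idealization of TIRF donor/acceptor trajectories with Viterbi
    decoding and dwell-time extraction, dwell-time exponential kinetics
    and transition-rate derivation under two-state and linear
    three-state models, complex-survival lifetime fitting and
    binding-isotherm Kd estimation. A seeded synthetic-data generator
    (continuous-time Markov conformational dynamics, camera-frame
    integration, Poisson photon emission with crosstalk and
    contaminants, binomial titration and survival series) emulates the
    experiments so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
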