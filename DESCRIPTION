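Package: hairwave
Title: Periodic Expression, Coupled Oscillators and Two-Population
    Deconvolution for the Mouse Hair Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for periodic gene expression in
    non-uniformly sampled hair-cycle time courses. Detects periodic
    transcripts by robust Fourier-series regression with Fisher's
    g-statistic and permutation p-values refined by a generalized Pareto
    tail, characterizes them as phase oscillators via the analytic
    signal, fits a two-group conformist/contrarian mean-field coupled
    oscillator model through its Ott-Antonsen reduction (with stability
    checks and a bifurcation scan), deconvolves bulk expression into an
    expanding and a static background cell population, and screens for
    negative-feedback candidate genes. Includes a seeded synthetic-data
    generator emulating the merged natural/induced hair-cycle design so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
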