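Package: plk4osc
Title: Receptor-Kinetics Models and Analysis of Plk4 Oscillations at the Centriole
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for the centriolar Plk4 oscillation that
    times centriole biogenesis in syncytial fly embryos. Implements a family of
    receptor-kinetics oscillator models (a linear S-phase binding/phosphorylation
    chain with an exact matrix-exponential solution, a multi-cycle variant with
    mitotic phosphatase resetting and an optional conserved cytosolic Plk4 pool,
    and a stochastic per-receptor Markov-chain model), nonlinear least-squares and
    Metropolis-Hastings fitting of these models to per-cycle fluorescence pulses,
    pulse regression (Lorentzian and alternatives) with amplitude, period and area
    extraction, centriole growth-curve analysis, prominence-based peak calling
    with unique peak-to-duplication matching and precision, recall and average-
    precision scoring, Otsu SNR classification of centriole fertility, Ripley-K
    spatial homogeneity tests, fluorescence correlation spectroscopy (ACF
    computation, eight diffusion and dark-state models with BIC selection,
    background correction, concentration estimation, robust outlier filtering),
    and peak counting spectroscopy (PeCoS) threshold calibration and counting.
    Seeded synthetic-data generators emulate every input so the full pipeline is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
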