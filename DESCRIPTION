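Package: masswave
Title: Half-Wave Decomposition and Stochastic Particle Models of Mass Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of physiological mass
    potentials (EEG, ECG, eye-blink EMG) as successions of half-waves.
    A record is segmented adaptively at zero-crossings and local minima of
    the rectified trace, each fragment is carried to the frequency domain
    with a Filon-type finite Fourier transform built from triangular basis
    functions, and the normalized amplitude spectrum is fitted with a
    Gaussian model whose cutoff frequency, together with a linear phase
    fit, yields the shape parameters (sigma, beta) of a closed-form
    half-wave function.  Records are reconstructed as sums of fitted
    half-wave functions, extension-ratio samples are compared across
    modalities with the two-sample Kolmogorov-Smirnov test, and a
    non-homogeneous birth-death Monte-Carlo simulator reproduces the
    half-wave function as the large-population limit of primary and
    secondary charged-particle populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
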