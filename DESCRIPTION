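Package: blowflyNS
Title: Hybrid Control of the Neimark-Sacker Bifurcation in the Discretized
    Nicholson's Blowflies Equation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stability and bifurcation analysis of the delayed Nicholson's
    blowflies equation under a hybrid control law combining parameter
    perturbation and delayed state feedback. Provides the closed-form Hopf
    analysis of the controlled delay differential equation (critical
    frequency, critical-delay sequence, transversality), two hybrid-control
    discretizations (a nonstandard finite-difference scheme with an
    exact-decay denominator function, and the forward Euler scheme) as step
    maps and trajectory simulators, numerical detection of the
    Neimark-Sacker critical delay for any step-size via the spectral radius
    of the linearization's companion matrix, and the normal-form
    classification (attracting or repelling invariant curve) of the
    bifurcation from the first Lyapunov-type coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
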