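Package: hetpattern
Title: Stochastic Turing Patterns of Heterocyst Development on Cell Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic and stochastic analysis of a three-morphogen
    reaction-diffusion model of heterocyst patterning in filamentous
    cyanobacteria: a non-diffusing activator (HetR) and two diffusing
    inhibitors (PatS, HetN) on a discrete one-dimensional chain of cells.
    Provides the chain Laplacian and its eigenmode transform, mean-field
    rate equations with equilibrium analysis, Turing linear stability and
    dispersion relations (discrete and continuum), exact Gillespie
    simulation of the underlying chemical master equation, linear-noise
    power spectra of demographic fluctuations, filament growth by cell
    duplication, and fluorescence-to-copy-number calibration by binomial
    partitioning statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
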