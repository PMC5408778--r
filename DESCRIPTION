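Package: phototcs
Title: Photoconversion Modeling and Light Program Design for Optogenetic
    Two-Component Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models wavelength- and intensity-dependent photoconversion of
    light-sensing bacterial two-component systems. Converts measured LED
    emission spectra into spectral flux densities and overlap-integral
    photoconversion rates, propagates two-state photoreceptor kinetics
    analytically under piecewise-constant light, and maps the active sensor
    ratio through a delayed Hill function into first-order output gene
    expression. Includes global nonlinear regression of the full model to
    characterization datasets, estimation of continuous photoconversion
    cross sections by constrained cubic-spline regression with
    leave-one-out cross-validated knot selection, a model-inverting light
    program generator for single and multiplexed gene-expression function
    generation, and a synthetic-data generator that reproduces the
    characterization experiment designs from known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
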