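Package: dnpid
Title: Divisive Normalization Processors: Simulation and Sparse Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the photoreceptor-amacrine cell layer of the fruit fly
    visual system as temporal and spatio-temporal divisive normalization
    processors (DNPs) built from first- and second-order Volterra kernels in
    trigonometric-polynomial reproducing kernel Hilbert spaces. Provides
    exact coefficient-domain forward simulators for the implicit
    divisive-feedback circuit, turns stimulus/response trials into a
    generalized-sampling measurement system, and identifies every circuit
    component by nuclear-norm (low-rank) convex optimization with a
    rank-truncated least-squares polish. Includes the printed example
    fixtures, synthetic stimulus generators, recovery diagnostics, and
    end-to-end scenario drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
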