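Package: mycelnet
Title: Morphometry and Micromechanics of Gradient Fibrous Mycelium Networks
Version: 0.1.0
Authors@R:
    person("Mycelnet", "Developers", email = "mycelnet@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of gradient porous mycelium tissue from
    SEM-style micrographs and micro-indentation records. Extracts fibrous-network
    microstructural descriptors (hyphal radii via distance-transform sampling
    along the skeleton with junction exclusion, Gaussian-mixture deconvolution of
    fiber types with AIC model selection, crosslink density, network density,
    segment length, pore-area statistics and porosity), estimates mesoscale
    elastic moduli from force-indentation curves through a contact-point-free
    derivative-form Hertz fit, and reports the structure-property gradient
    (modulus versus crosslink density) across growth layers. Ships a synthetic
    fiber-network and indentation-curve generator with analytic ground truth so
    the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
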