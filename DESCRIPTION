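Package: dcslayers
Title: Layered Monte Carlo and Multilayer Diffusion Models for Diffuse
    Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for diffuse correlation
    spectroscopy (DCS) measurements of cerebral blood flow. Provides a
    compiled Monte Carlo photon transport engine for layered slab and
    concentric-sphere head models that records per-layer pathlengths and
    momentum transfer of detected photons, forward synthesis of intensity
    autocorrelation curves via the Siegert relation, semi-infinite and
    three-layer solutions of the correlation diffusion equation, inverse
    fitting of scalp and cerebral blood flow indices, a pressure-modulation
    search for equivalent layer thicknesses, and error metrics for absolute
    and relative blood flow recovery across scalp/brain flow grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
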