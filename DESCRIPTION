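Package: mtarray
Title: Monte Carlo Simulation of Cellular Microtubule Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic fixed-time-step simulation of an interphase
    microtubule array nucleated from a fixed pool of centrosomal sites
    inside a confined cell boundary. Microtubule plus ends switch between
    growth and shortening (dynamic instability) with measured catastrophe
    and rescue frequencies; growth velocity is proportional to the free
    tubulin concentration, which is closed under an exact monomer-polymer
    mass balance. Supports multi-stage protocols (nucleation shutoff,
    tubulin dilution, interphase-to-prophase parameter switches), a
    two-zone catastrophe landscape, per-step parameter and boundary noise,
    steady-state and length-distribution analyses, pre-built experiment
    recipes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
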