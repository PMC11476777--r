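Package: budmorph
Title: Multiscale Mechano-Chemical Simulation of Yeast Bud Morphogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Three-dimensional coarse-grained simulation of budding in
    Saccharomyces cerevisiae. The cell surface is a closed triangulated
    elastic network (linear stretching springs, cosine bending hinges,
    harmonic area resistance, Morse self-avoidance) inflated by constant
    turgor pressure and evolved by overdamped dynamics. Bud growth is
    modelled as periodic insertion of new surface material by triangle-pair
    splitting, gated by a Cdc42 activator / global-inhibitor
    reaction-diffusion system solved quasi-statically on the deforming
    surface with a cotangent Laplace-Beltrami operator, and the mesh is
    relaxed by Metropolis edge flipping. Includes scenario presets for
    spherical versus tubular budding, shape metrics (bud area, aspect
    ratio, polarization height), and PLY/OFF/VTK snapshot writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
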