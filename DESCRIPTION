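Package: lumensim
Title: Hybrid Deformable-Cell and Center-Based Simulation of Bile Duct
    Lumen Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of early bile-duct lumenogenesis around
    the embryonic portal vein. Cells near the forming lumen are resolved as
    deformable cortex rings (in-plane elasticity, bending, volume control,
    cohesive-zone adhesion, apico-basal and planar polarity, tight junctions,
    apical constriction, tracer-particle osmosis), coupled mechanically to a
    center-based model with a calibrated JKR contact law for the endothelium
    and far-field hepatoblasts. Includes the idealized bilayer and
    portal-vein duct experiment families (oriented division, apical
    constriction, osmotic loading; model variants 0-3), a proliferation-rate
    controller, hepatoblast-to-cholangiocyte differentiation, lumen-area and
    apical/basal morphometry, ensemble statistics, and VTK/CSV/JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
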