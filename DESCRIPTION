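Package: hbflow
Title: Herschel-Bulkley Blood Flow in Tapered Arteries with Stenosis and
    Dilatation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Steady, axisymmetric flow of a Herschel-Bulkley (yield-stress,
    power-law) fluid through a slowly tapering tube carrying cosine-shaped
    abnormal wall segments (stenoses and post-stenotic dilatations), in the
    lubrication (mild-stenosis) limit. Computes the plug-core velocity
    profile, stream function, the pressure gradient for a prescribed flow
    rate (by Newton-Raphson solution of the implicit flow-rate relation, or
    from a small-yield-stress expansion), wall shear stress, and cumulative
    flow resistance along the vessel. The fitted-model object carries the
    axial profiles and supports the usual print, summary, coef, predict,
    residuals and plot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
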