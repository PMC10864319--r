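Package: shakeflask
Title: Liquid Distribution and Power Input in Orbitally Shaken Flasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the hydrodynamics of orbitally shaken shake flasks:
    a parametric model of the inner flask wall (quarter-torus plus cone,
    with either a sharp or a tangency-smoothed transition), the inviscid
    mechanistic model of the rotating liquid distribution obtained by
    intersecting a centrifugal paraboloid with the flask wall under a
    volume-matching constraint, probe-based extraction of liquid contact
    lines and wall-film diagnostics from volume-of-fluid fields,
    volumetric power input from energy-dissipation fields and from the
    modified Newton number versus Reynolds number correlation, and a
    synthetic volume-of-fluid field generator with analytic ground truth
    for testing the extraction and dissipation stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
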