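Package: dcmorph
Title: Quantitative Analysis of Dermal Condensate Morphogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how mesenchymal (dermal) condensates form
    beneath developing hair-follicle placodes. Implements drift correction and
    motility metrics (velocity, net velocity, straightness, escape angle) for
    3D cell tracks, circular statistics (Rayleigh Z, two-sample Watson U2, a
    3D uniform-on-sphere null), point-cloud density / nearest-neighbour /
    label-fraction analyses, 3D nuclear morphometry (volume, surface area,
    Wadell sphericity) on label volumes, normality-gated assay statistics
    (scratch-wound closure, transwell migration, delta-delta-Ct), and an
    agent-based simulator of the three classical condensation mechanisms
    (proliferation, directed migration, non-dispersal) that generates fully
    synthetic tracks, scenes and label volumes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
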