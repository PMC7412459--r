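Package: leafcmq
Title: Conceptual Midpoint Quasi-Color Modeling of Bifacial Leaves
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modeling the conceptual midpoint quasi-color (CMQ) of
    bifacial plant leaves from nondestructive pigment meter readings. The CMQ
    is a notional CIELab color whose coordinates are the per-axis means of the
    colors measured at antipodal points on the adaxial and abaxial leaf
    surfaces; it links leaf chlorophyll (SPAD) and anthocyanin (ACI) indices
    to whole-leaf coloration even when the two surfaces differ strongly.
    Provides CIELab arithmetic (chroma, hue with a wraparound convention,
    color difference), the published three-hidden-node hyperbolic-tangent
    network predictor, training of such networks and of polynomial baselines
    with repeated cross-validated hidden-node selection, agreement metrics
    (including Lin's concordance), quasi-color gamut mapping over pigment
    grids, inference of an unobserved leaf surface from the observed one, a
    synthetic leaf-data generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), nnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
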