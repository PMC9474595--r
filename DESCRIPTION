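Package: pelviplan
Title: Automated Four-Field-Box and 3D-Conformal Pelvic Radiotherapy Planning
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated external-beam plan generation for cervical cancer
    at desk scale. Generates a parameterized synthetic pelvic phantom (binary
    structure masks on a regular voxel grid), designs 4-field-box beam
    apertures from projected bony landmarks and 3D-CRT apertures from the
    projected planning target volume, computes dose with a declared simplified
    6 MV photon surrogate engine (depth falloff, penumbra, MU linearity),
    reduces hot spots with automated field-in-field forward optimization,
    normalizes plans by isodose coverage of a target volume, and evaluates
    dose-volume histogram metrics against EMBRACE II-style hard and soft
    constraints. Millimeter-true mask morphology (margin expansion, erosion,
    beam's-eye-view projection) is implemented with exact Euclidean distance
    transforms in compiled code.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
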