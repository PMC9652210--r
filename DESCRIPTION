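Package: acetav
Title: True Three-Dimensional Acetabular Anteversion from Pelvis Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the acetabular anteversion (AV) angle of the hip socket
    directly on three-dimensional pelvis surface meshes, independent of patient
    positioning. The acetabular rim is delineated as the high-curvature crest of
    the triangle mesh, a robust circle is fitted to the rim with iterative
    outlier rejection, and the AV angle is obtained as the complement of the
    angle between the acetabular plane normal and the anterior pelvic plane
    normal (AV = 90 - alpha). The classical 2D axial-slice measurements (the
    posterior-margin referenced and the femoral-head-centre referenced
    variants) are emulated on mesh cross-sections, a virtual pelvic-tilt
    simulation quantifies their pose dependence, and a statistics layer
    (group summaries, Welch t-tests, single/multiple/interaction regression of
    the 3D-2D discrepancy on pelvic pose angles) mirrors a cohort analysis.
    A parametric hemipelvis phantom with exact analytic ground truth and a
    cohort simulator make every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
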