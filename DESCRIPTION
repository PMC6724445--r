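Package: vesselreg
Title: Rigid 2D/3D Registration of Coronary Artery Centerlines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rapid rigid registration of a preoperative 3D coronary-artery
    centerline tree (from CT angiography) onto an intraoperative 2D vessel
    centerline (from an X-ray angiogram frame). Implements ECG-based cardiac
    phase matching for frame selection, anatomy-driven importance weighting
    of centerline points, C-arm perspective projection from acquisition
    metadata, bounding-box translation initialization, a capped local
    distance map built by 8-neighbor chamfer propagation, an importance
    weighted selective distance similarity (AADD), and staged bounded Powell
    optimization of the six rigid pose parameters. Includes a synthetic-data
    generator (parametric vessel trees, C-arm geometry, rendered centerline
    rasters under known ground-truth poses, synthetic ECG) and accuracy
    metrics against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    signal,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    yaml,
    stats,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
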