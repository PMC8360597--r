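Package: fmrivine
Title: Persistence Vineyards and Task-Responsiveness Tests for fMRI Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers and tests time-dynamic topological structure in
    task-based fMRI signals. Voxel tables (x, y, z, amplitude; one table per
    time index) are normalized into a four-dimensional "stereotactic
    hyperspace" by a parameterless linear rescaling of the amplitude, and the
    Vietoris-Rips persistent homology of the resulting point cloud is computed
    at each time index with a hard maximum-radius truncation, including a
    representative cycle for every loop class. Per-timepoint persistence
    diagrams are stacked into vineyards whose inter-timepoint edges are shaded
    by the three-dimensional Hausdorff distance between representative loops;
    spatially constrained, possibly intermittent "vines" are extracted and
    tested for task-responsiveness with a Wasserstein-distance group statistic
    under block-respecting label permutation. Includes deterministic synthetic
    generators (displaced-center cube, cylinder surface, low-amplitude ring,
    block-design task series) and a brute-force rank-based persistence oracle
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
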