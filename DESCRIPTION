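Package: rhizotrack
Title: Growth Tracking and Trait Quantification for 3D Voxel Root Time-Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the growth history of a plant root system from a
    time-series of 3D voxelized shapes. Shapes are rigidly registered into a
    common frame (coarse 4-point congruent sets search followed by iterative
    closest point refinement), a seed area is detected and propagated through
    the series, geodesic depth is computed on the 26-connected voxel graph,
    and the final shape is decomposed into a hierarchy of branches by a
    pointer-merge traversal in decreasing depth. A per-voxel creation-time
    function is reconstructed by back-to-front branch matching and repaired
    where the depth hierarchy contradicts observed growth order. From the
    resulting growth record the package computes per-branch structural and
    dynamic traits (volume, length, tortuosity, radius, angles, branching),
    seed traits, and whole-system aggregates. A swept-tube simulator
    generates ground-truthed synthetic root systems for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
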