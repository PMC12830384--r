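Package: aggseg
Title: Geometry-Aware Segmentation of Aggregate Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments a 3D point cloud of an aggregate of near-spherical
    components (a grape bunch, a box of tomatoes) into its individual
    components and fits one template mesh per component. The pipeline
    normalizes and voxel-downsamples the cloud, over-clusters it with
    k-means, fits a sphere (or a user template) to every cluster by RANSAC
    hypothesis generation with greedy Chamfer-distance refinement, merges
    clusters whose fitted components overlap until a fixpoint, and finally
    refines each component with per-axis scaling and small rotations.
    Includes a ground-truthed synthetic aggregate generator emulating
    structure-from-motion output (noise, nonuniform density, occlusion),
    evaluation metrics (recovered component count, normalized
    center-to-center distances), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
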