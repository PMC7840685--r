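Package: fractalarbor
Title: Fractal Geometry, Connectivity and Cost Analysis of Dendritic Arbors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the fractal geometry of neuronal dendritic
    arbors and relating it to network connectivity and wiring costs. Provides a
    centerline (SWC) and triangle-mesh (Wavefront OBJ) data model for arbors,
    exact surface voxelization, three-dimensional sliding box-counting with
    scaling-range selection to estimate an effective fractal dimension,
    orientation-averaged connectivity profiles from orthographic projections
    over Fibonacci-lattice viewpoints, convex-hull bounding metrics, branch
    angle manipulation by rigid subtree rotations, H-tree and toy-arbor
    generators (including weaving branches driven by fractional Gaussian
    noise), and a pipeline that fits cost and connectivity metrics against
    fractal dimension and locates the optima of their derivative ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
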