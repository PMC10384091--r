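Package: fishlen
Title: Non-Contact Underwater Fish Body-Length Measurement from RGB-D Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the body length of fish swimming below a flat air-water
    interface from aligned RGB and depth (RGB-D) images taken by a stereo
    camera above the surface. Implements contrast-adaptive GrabCut
    segmentation driven by a user region of interest, bend-state
    classification from the minimum-area bounding rectangle, skeleton-based
    straightening of curved fish (Zhang-Suen thinning with corner removal and
    burr pruning), and Snell's-law refraction correction of the stereo depth
    and of the back-projected 3D coordinates. Ships a physics-based synthetic
    scene generator (exact refractive ray tracing of a pinhole stereo pair)
    that provides ground-truthed fixtures for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    grDevices,
    EBImage,
    igraph,
    png,
    tiff,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Segmentation
RoxygenNote: 7.3.3
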