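Package: msccd
Title: Multiscale Centroid Contour Distance Descriptors for Shape Retrieval
Version: 0.1.0
Authors@R:
    person("Shape", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Contour-based shape description and retrieval for biological
    silhouettes such as leaf outlines. Implements the centroid contour
    distance (CCD) signature, its multiscale extension built on dynamic
    (windowed) centroids (MSCCD), the angle-scale descriptor (ASD), and
    their Fourier-magnitude counterparts (FCCD, FMSCCD, FASD), together
    with cyclic-shift-invariant matching distances, weighted multiscale
    and combined dissimilarities, and the standard retrieval evaluation
    protocols (bulls-eye score, precision at fixed recall, top-k hit
    counts, intra/inter-class distance statistics). Includes binary-mask
    boundary tracing, uniform arc-length resampling, a seeded generator
    of parametric synthetic shape databases, and a command-line
    interface for end-to-end reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
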