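Package: gcfe
Title: Gershgorin Circle Feature Extraction for Image Patch Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduces image patches to compact spectral features via the
    Gershgorin circle theorem.  Images are normalized, partitioned into
    non-overlapping patches, and each patch is converted to a weighted
    graph (2D-grid lattice, complete pairwise, or K-nearest-neighbour in
    intensity space) whose modified weighted Laplacian -- unweighted
    degrees minus weighted adjacency -- is diagonally dominant and
    positive semi-definite.  Each N x N Laplacian collapses to N
    (radius, center) pairs bounding its eigenvalues, giving a P x N x 2
    representation whose size is independent of patch size.  Also
    provides declarative 1D/2D convolutional network architecture specs
    with analytic trainable-parameter counting, the reporting statistics
    used to benchmark the method (sample standard deviation, symmetric
    percentage difference, Z-score), deterministic synthetic image
    fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    withr,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    png,
    tiff,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
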