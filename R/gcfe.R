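#' Gershgorin radii of a square matrix
#'
#' `r_i` is the absolute sum of row i's off-diagonal entries. For the
#' modified weighted Laplacian these radii, paired with the diagonal
#' centers, bound every eigenvalue on the real axis.
#'
#' @param l A square numeric matrix.
#' @return Numeric vector of length nrow(l), all entries >= 0.
#' @export
gershgorin_radii <- function(l) {
  stopifnot(is.matrix(l), nrow(l) == ncol(l))
  rowSums(abs(l)) - abs(diag(l))
}

#' Gershgorin centers of a square matrix
#'
#' The diagonal entries `c_i = L[i, i]`; for the modified weighted Laplacian
#' these equal the unweighted node degrees.
#'
#' @param l A square numeric matrix.
#' @return Numeric vector of length nrow(l).
#' @export
gershgorin_centers <- function(l) {
  stopifnot(is.matrix(l), nrow(l) == ncol(l))
  diag(l)
}

#' Gershgorin circle feature extraction
#'
#' Runs the full pipeline on one image: grayscale reduction (for RGB
#' input), fixed-range normalization to \[0, 1\], partition into
#' non-overlapping `patch_size` x `patch_size` tiles, conversion of each
#' tile to a weighted graph, formation of the modified weighted Laplacian
#' L = D - A (unweighted degrees, weighted adjacency), and reduction of
#' each Z x Z Laplacian to its Z Gershgorin (radius, center) pairs. The
#' result is a P x N x 2 array — P patches, N = patch_size^2 nodes per
#' patch — whose total element count 2 M N is independent of the patch
#' size chosen.
#'
#' Because L is diagonally dominant with nonnegative diagonal, every disc
#' interval \[c_i - r_i, c_i + r_i\] lies on the nonnegative real axis and
#' their union contains every eigenvalue of L. The reduction is
#' deterministic and irreversible.
#'
#' @param img Matrix (grayscale) or M x N x 3 array (RGB) of 0-255
#'   intensities.
#' @param patch_size Side length of the square patches; must divide both
#'   image dimensions.
#' @param graph_type `"grid2d"` (4-connected lattice), `"pairwise"`
#'   (complete graph), or `"knn"`.
#' @param knn_k Neighbour count for the knn graph; defaults to
#'   `patch_size`, matching the convention of selecting K equal to the
#'   patch size.
#' @param grayscale Convert RGB input to luminance first (default TRUE;
#'   required, since edge weights are scalar intensity differences).
#' @return An object of class `"gcfe"`: a list with `features` (P x N x 2
#'   array; slice 1 radii, slice 2 centers), `radii` and `centers` (P x N
#'   matrices), `patch_size`, `graph_type`, `knn_k`, `dims`, `n_patches`,
#'   `n_nodes`.
#' @examples
#' img <- synth_image("checkerboard", 4, 4)
#' f <- gcfe(img, patch_size = 2, graph_type = "pairwise")
#' f$centers  # every pixel of a 2x2 patch has degree 3 in K4
#' @export
gcfe <- function(img, patch_size,
                 graph_type = c("grid2d", "pairwise", "knn"),
                 knn_k = NULL, grayscale = TRUE) {
  graph_type <- match.arg(graph_type)
  if (grayscale) img <- to_grayscale(img)
  if (!is.matrix(img)) {
    stop("multi-channel input requires `grayscale = TRUE`", call. = FALSE)
  }
  norm <- normalize_minmax(img)
  ps <- partition_patches(norm, patch_size)
  if (graph_type == "knn" && is.null(knn_k)) knn_k <- ps$patch_size
  n_nodes <- ps$patch_size * ps$patch_size  # integer, = Z nodes per patch
  n_patches <- length(ps$patches)
  radii <- matrix(NA_real_, n_patches, n_nodes)
  centers <- matrix(NA_real_, n_patches, n_nodes)
  for (idx in seq_len(n_patches)) {
    g <- build_patch_graph(ps$patches[[idx]], graph_type, k = knn_k)
    l <- mwl(g)
    radii[idx, ] <- gershgorin_radii(l)
    centers[idx, ] <- gershgorin_centers(l)
  }
  features <- array(c(radii, centers), dim = c(n_patches, n_nodes, 2L),
                    dimnames = list(NULL, NULL, c("radius", "center")))
  structure(
    list(features = features, radii = radii, centers = centers,
         patch_size = ps$patch_size, graph_type = graph_type,
         knn_k = if (graph_type == "knn") knn_k else NULL,
         dims = ps$dims, n_patches = n_patches, n_nodes = n_nodes),
    class = "gcfe"
  )
}

#' Flatten GC features to a single vector
#'
#' Stacks each patch's radius and center vectors in patch order. With
#' `order = "interleaved"` (default) the layout is
#' \[R1, C1, R2, C2, ...\], keeping each patch's two vectors adjacent;
#' `order = "blocked"` emits all radii first, then all centers. Both are
#' permutations of the same 2 P N values.
#'
#' @param x A `gcfe` object.
#' @param order `"interleaved"` or `"blocked"`.
#' @return Numeric vector of length 2 * P * N.
#' @export
gcfe_layout_1d <- function(x, order = c("interleaved", "blocked")) {
  stopifnot(inherits(x, "gcfe"))
  order <- match.arg(order)
  if (order == "blocked") {
    return(c(t(x$radii), t(x$centers)))
  }
  out <- numeric(2L * x$n_patches * x$n_nodes)
  pos <- 0L
  for (idx in seq_len(x$n_patches)) {
    out[pos + seq_len(x$n_nodes)] <- x$radii[idx, ]
    pos <- pos + x$n_nodes
    out[pos + seq_len(x$n_nodes)] <- x$centers[idx, ]
    pos <- pos + x$n_nodes
  }
  out
}

#' Arrange GC features as a two-row plane
#'
#' Row 1 holds the radii of all patches concatenated in patch order, row 2
#' the centers, with a trailing singleton channel axis — the (2, P*N, 1)
#' input plane of the 2-D convolutional classifier.
#'
#' @param x A `gcfe` object.
#' @return A 2 x (P*N) x 1 array.
#' @export
gcfe_layout_2d <- function(x) {
  stopifnot(inherits(x, "gcfe"))
  plane <- rbind(c(t(x$radii)), c(t(x$centers)))
  array(plane, dim = c(2L, x$n_patches * x$n_nodes, 1L))
}

#' @export
print.gcfe <- function(x, ...) {
  cat(sprintf(
    "Gershgorin circle features (%s graph%s)\n",
    x$graph_type,
    if (!is.null(x$knn_k)) paste0(", k = ", x$knn_k) else ""
  ))
  cat(sprintf("  image: %d x %d, patch size %d\n",
              x$dims[1L], x$dims[2L], x$patch_size))
  cat(sprintf("  features: %d patches x %d nodes x 2 (radius, center)\n",
              x$n_patches, x$n_nodes))
  invisible(x)
}

#' @export
summary.gcfe <- function(object, ...) {
  x <- object
  cat(sprintf("GC features: P = %d patches, N = %d nodes, %d values total\n",
              x$n_patches, x$n_nodes, 2L * x$n_patches * x$n_nodes))
  cat(sprintf("  radii:   [%.4f, %.4f], mean %.4f\n",
              min(x$radii), max(x$radii), mean(x$radii)))
  cat(sprintf("  centers: [%g, %g] (degrees), sum %g = 2|E| per image\n",
              min(x$centers), max(x$centers), sum(x$centers)))
  cat(sprintf("  dominance margin min(c - r): %.4f\n",
              min(x$centers - x$radii)))
  invisible(x)
}

#' Matrix view of GC features
#'
#' @param x A `gcfe` object.
#' @param ... Unused.
#' @return A (P*N) x 2 matrix with columns `radius` and `center`, rows in
#'   patch-major node order.
#' @export
as.matrix.gcfe <- function(x, ...) {
  cbind(radius = c(t(x$radii)), center = c(t(x$centers)))
}

#' Plot Gershgorin discs of extracted features
#'
#' Draws each node's disc — center `(c_i, 0)`, radius `r_i` — in the
#' complex plane for one or more patches. Since the underlying Laplacians
#' are diagonally dominant, every disc touches or avoids the origin from
#' the right: all eigenvalues are real and nonnegative.
#'
#' @param x A `gcfe` object.
#' @param patches Indices of patches to draw (default: first patch).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gcfe <- function(x, patches = 1L, ...) {
  stopifnot(all(patches >= 1L), all(patches <= x$n_patches))
  r <- x$radii[patches, , drop = FALSE]
  cc <- x$centers[patches, , drop = FALSE]
  xlim <- range(cc - r, cc + r)
  ylim <- c(-1, 1) * max(r, 0.5)
  graphics::plot(NA, xlim = xlim, ylim = ylim, asp = 1,
                 xlab = "Re", ylab = "Im",
                 main = "Gershgorin discs of the modified weighted Laplacian",
                 ...)
  graphics::abline(h = 0, col = "grey70")
  cols <- grDevices::hcl.colors(max(length(patches), 2L), "Dark 2")
  for (pi in seq_along(patches)) {
    graphics::symbols(cc[pi, ], rep(0, ncol(cc)), circles = pmax(r[pi, ], 1e-3),
                      inches = FALSE, add = TRUE, fg = cols[pi])
  }
  graphics::points(c(cc), rep(0, length(cc)), pch = 3)
  invisible(x)
}
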