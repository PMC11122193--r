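#' Edge weight between two pixels
#'
#' The absolute intensity difference `|v2 - v1|`. On normalized pixels this
#' lies in \[0, 1\], is symmetric in its arguments, and is zero exactly for
#' equal intensities.
#'
#' @param v1,v2 Pixel intensities in \[0, 1\]; vectorized.
#' @return Nonnegative weight(s).
#' @export
edge_weight <- function(v1, v2) abs(v2 - v1)

# internal constructor: edges as a data.frame(i, j, w) with i < j, no dups
new_patch_graph <- function(n_nodes, edges, type, k = NULL) {
  stopifnot(all(edges$i < edges$j), !anyDuplicated(edges[c("i", "j")]))
  structure(
    list(n_nodes = as.integer(n_nodes), edges = edges, type = type, k = k),
    class = "patch_graph"
  )
}

patch_values <- function(patch) as.vector(t(patch))  # row-major node order

#' Convert a patch to a 2D-grid lattice graph
#'
#' Pixels become nodes in row-major order; edges connect horizontally and
#' vertically adjacent pixels (4-connectivity), so a p x p patch has
#' 2p(p - 1) edges. Edge weights are absolute intensity differences.
#'
#' @param patch Numeric p x p matrix with values in \[0, 1\].
#' @return A `patch_graph`.
#' @export
build_grid2d <- function(patch) {
  stopifnot(is.matrix(patch))
  nr <- nrow(patch)
  nc <- ncol(patch)
  v <- patch_values(patch)
  node <- function(r, c) (r - 1L) * nc + c
  is <- integer(0)
  js <- integer(0)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (c < nc) { is <- c(is, node(r, c)); js <- c(js, node(r, c + 1L)) }
      if (r < nr) { is <- c(is, node(r, c)); js <- c(js, node(r + 1L, c)) }
    }
  }
  edges <- data.frame(i = is, j = js, w = edge_weight(v[is], v[js]))
  new_patch_graph(nr * nc, edges, "grid2d")
}

#' Convert a patch to a complete pairwise graph
#'
#' Every pair of pixels is connected, giving Z(Z - 1)/2 edges on the
#' Z = p^2 nodes. On a 2 x 2 patch this is K4: every node has degree 3.
#'
#' @inheritParams build_grid2d
#' @return A `patch_graph`.
#' @export
build_pairwise <- function(patch) {
  stopifnot(is.matrix(patch))
  z <- length(patch)
  v <- patch_values(patch)
  if (z < 2L) {
    edges <- data.frame(i = integer(0), j = integer(0), w = numeric(0))
  } else {
    pairs <- utils::combn(z, 2L)
    edges <- data.frame(i = pairs[1L, ], j = pairs[2L, ],
                        w = edge_weight(v[pairs[1L, ]], v[pairs[2L, ]]))
  }
  new_patch_graph(z, edges, "pairwise")
}

#' Convert a patch to a K-nearest-neighbour graph in intensity space
#'
#' Each node proposes edges to the k other nodes with the smallest absolute
#' intensity difference; ties are broken by ascending node index. The edge
#' set is the symmetrized union of all proposals, so realized degrees can
#' exceed k. With k = Z - 1 the result equals the pairwise graph.
#'
#' @inheritParams build_grid2d
#' @param k Number of neighbours per node, 1 <= k <= Z - 1.
#' @return A `patch_graph`.
#' @export
build_knn <- function(patch, k) {
  stopifnot(is.matrix(patch))
  z <- length(patch)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > z - 1L) {
    stop(sprintf("k must satisfy 1 <= k <= %d (Z - 1); got %s", z - 1L, k),
         call. = FALSE)
  }
  v <- patch_values(patch)
  picked <- matrix(0L, nrow = 0L, ncol = 2L)
  for (i in seq_len(z)) {
    others <- setdiff(seq_len(z), i)
    ord <- others[order(abs(v[others] - v[i]), others)]
    nb <- ord[seq_len(k)]
    picked <- rbind(picked, cbind(pmin(i, nb), pmax(i, nb)))
  }
  picked <- unique(as.data.frame(picked))
  names(picked) <- c("i", "j")
  picked <- picked[order(picked$i, picked$j), , drop = FALSE]
  rownames(picked) <- NULL
  edges <- data.frame(i = picked$i, j = picked$j,
                      w = edge_weight(v[picked$i], v[picked$j]))
  new_patch_graph(z, edges, "knn", k = k)
}

#' Build a patch graph of a chosen type
#'
#' Dispatch helper over the three supported graph constructions.
#'
#' @inheritParams build_grid2d
#' @param type One of `"grid2d"`, `"pairwise"`, `"knn"`.
#' @param k Neighbour count, required for `"knn"`.
#' @return A `patch_graph`.
#' @export
build_patch_graph <- function(patch, type = c("grid2d", "pairwise", "knn"),
                              k = NULL) {
  type <- match.arg(type)
  switch(type,
    grid2d   = build_grid2d(patch),
    pairwise = build_pairwise(patch),
    knn      = {
      if (is.null(k)) stop("`k` is required for the knn graph type",
                           call. = FALSE)
      build_knn(patch, k)
    }
  )
}

#' @export
print.patch_graph <- function(x, ...) {
  cat(sprintf("Patch graph (%s%s): %d nodes, %d edges\n",
              x$type, if (!is.null(x$k)) paste0(", k = ", x$k) else "",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Export a patch graph as an edge-list data frame
#'
#' @param x A `patch_graph`.
#' @param ... Unused.
#' @return A data.frame with columns `i`, `j`, `w`.
#' @export
as.data.frame.patch_graph <- function(x, ...) x$edges
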