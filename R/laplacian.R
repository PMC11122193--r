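#' Weighted adjacency matrix of a patch graph
#'
#' `A[i, j] = W_ij` for edges `(i, j)`, zero elsewhere. Symmetric with zero
#' diagonal. Note that an edge whose endpoints share the same intensity is
#' structurally present but contributes a numerical zero here.
#'
#' @param g A `patch_graph`.
#' @return A Z x Z numeric matrix.
#' @export
weighted_adjacency <- function(g) {
  stopifnot(inherits(g, "patch_graph"))
  a <- matrix(0, g$n_nodes, g$n_nodes)
  if (nrow(g$edges)) {
    a[cbind(g$edges$i, g$edges$j)] <- g$edges$w
    a[cbind(g$edges$j, g$edges$i)] <- g$edges$w
  }
  a
}

#' Unweighted (binary) adjacency matrix of a patch graph
#'
#' `S[i, j] = 1` exactly when `(i, j)` is an edge, including zero-weight
#' edges between equal-intensity pixels.
#'
#' @param g A `patch_graph`.
#' @return A Z x Z 0/1 matrix.
#' @export
unweighted_adjacency <- function(g) {
  stopifnot(inherits(g, "patch_graph"))
  s <- matrix(0, g$n_nodes, g$n_nodes)
  if (nrow(g$edges)) {
    s[cbind(g$edges$i, g$edges$j)] <- 1
    s[cbind(g$edges$j, g$edges$i)] <- 1
  }
  s
}

#' Degree matrix from a binary adjacency matrix
#'
#' Diagonal matrix whose entry `D[i, i]` is the number of edges incident to
#' node i (the row sum of S).
#'
#' @param s A binary adjacency matrix.
#' @return A diagonal matrix of the same size.
#' @export
degree_matrix <- function(s) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  diag(rowSums(s), nrow(s))
}

#' Modified weighted Laplacian of a patch graph
#'
#' `L = D - A`, where A is the weighted adjacency but D holds the
#' *unweighted* degrees (edge counts). Because every weight is at most 1
#' while each edge contributes exactly 1 to its endpoints' degrees, each
#' diagonal entry dominates its row's absolute off-diagonal sum — strictly
#' whenever some incident weight is below 1. The matrix is therefore
#' symmetric, (weakly) diagonally dominant with nonnegative diagonal, and
#' positive semi-definite.
#'
#' @param g A `patch_graph`.
#' @return A Z x Z numeric matrix.
#' @export
mwl <- function(g) {
  degree_matrix(unweighted_adjacency(g)) - weighted_adjacency(g)
}
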