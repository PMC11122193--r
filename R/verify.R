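#' Run the package's structural invariant suite
#'
#' Checks, on seeded random patches of sizes 2-8 under all three graph
#' types, the properties the feature extraction is built on:
#' \itemize{
#'   \item every eigenvalue of the modified weighted Laplacian (dense
#'     eigensolver) lies in the union of its Gershgorin intervals
#'     \[c_i - r_i, c_i + r_i\] and is >= -1e-9 (PSD);
#'   \item the Laplacian is symmetric and weakly diagonally dominant,
#'     strictly on every row with an incident weight below 1;
#'   \item trace(L) = 2|E| (handshake identity);
#'   \item the feature array has shape P x N x 2 and total length 2 M N
#'     regardless of patch size.
#' }
#'
#' @param n_patches_per_case Random patches per (size, graph type) pair.
#' @param seed Seed for patch generation.
#' @return TRUE invisibly if every check passes; otherwise an error
#'   describing the first failure.
#' @export
gcfe_verify <- function(n_patches_per_case = 10L, seed = 1L) {
  fail <- function(...) stop(sprintf(...), call. = FALSE)
  for (p in 2:8) {
    for (type in c("grid2d", "pairwise", "knn")) {
      for (rep in seq_len(n_patches_per_case)) {
        case_seed <- seed + 1000L * p + 100L * rep +
          match(type, c("grid2d", "pairwise", "knn"))
        patch <- normalize_minmax(
          synth_image("random", p, p, seed = case_seed))
        g <- build_patch_graph(patch, type, k = min(p, p^2 - 1L))
        l <- mwl(g)
        if (max(abs(l - t(l))) > 0) fail("asymmetric L (p=%d, %s)", p, type)
        r <- gershgorin_radii(l)
        ctr <- gershgorin_centers(l)
        if (any(ctr - r < -1e-12)) {
          fail("diagonal dominance violated (p=%d, %s)", p, type)
        }
        a <- weighted_adjacency(g)
        strict_rows <- rowSums(unweighted_adjacency(g) > 0 & a < 1) > 0
        if (any(strict_rows & !(ctr - r > 1e-12) & ctr > 0)) {
          fail("strict dominance missing on a row with weight < 1 (p=%d, %s)",
               p, type)
        }
        if (abs(sum(diag(l)) - 2 * nrow(g$edges)) > 1e-9) {
          fail("trace(L) != 2|E| (p=%d, %s)", p, type)
        }
        ev <- eigen(l, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < -1e-9) fail("L not PSD (p=%d, %s)", p, type)
        covered <- vapply(ev, function(lam) {
          any(lam >= ctr - r - 1e-9 & lam <= ctr + r + 1e-9)
        }, logical(1))
        if (!all(covered)) {
          fail("eigenvalue outside Gershgorin union (p=%d, %s)", p, type)
        }
      }
    }
  }
  # feature-shape invariance across patch sizes on one image
  img <- synth_image("random", 8L, 8L, seed = seed)
  for (p in c(1L, 2L, 4L, 8L)) {
    if (p == 1L) next  # single-node graphs need no divisor check here
    f <- gcfe(img, p, "grid2d")
    if (!identical(dim(f$features),
                   c(f$n_patches, f$n_nodes, 2L))) {
      fail("feature array is not P x N x 2 (p=%d)", p)
    }
    if (length(f$features) != 2L * 64L) {
      fail("total feature length depends on patch size (p=%d)", p)
    }
  }
  invisible(TRUE)
}
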