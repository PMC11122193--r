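checker2 <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)

test_that("radii and centers read off the Laplacian rows", {
  l <- mwl(build_pairwise(checker2))
  expect_equal(gershgorin_radii(l), rep(2, 4))
  expect_equal(gershgorin_centers(l), rep(3, 4))
  l_grid <- mwl(build_grid2d(checker2))
  expect_equal(gershgorin_centers(l_grid), rep(2, 4))  # 4-cycle degrees
  l_const <- mwl(build_pairwise(matrix(0.2, 2, 2)))
  expect_equal(gershgorin_radii(l_const), rep(0, 4))
  l1 <- mwl(build_pairwise(matrix(0.2, 1, 1)))
  expect_equal(gershgorin_radii(l1), 0)
  expect_equal(gershgorin_centers(l1), 0)
})

test_that("end-to-end extraction yields the P x N x 2 array", {
  f <- gcfe(synth_image("random", 28, 28, seed = 9), 2, "grid2d")
  expect_s3_class(f, "gcfe")
  expect_equal(dim(f$features), c(196L, 4L, 2L))
  expect_identical(f$features[, , 1], f$radii)
  expect_identical(f$features[, , 2], f$centers)
  # constant image: zero radii, degree centers
  fc <- gcfe(synth_image("constant", 4, 4), 2, "grid2d")
  expect_true(all(fc$radii == 0))
  expect_true(all(fc$centers == 2))
})

test_that("pairwise 2x2 patches always center at degree 3", {
  f <- gcfe(fig_sample_4x4(), 2, "pairwise")
  expect_equal(dim(f$features), c(4L, 4L, 2L))
  expect_true(all(f$centers == 3))
  expect_true(all(f$radii <= 3))
})

test_that("total feature count is 2MN regardless of patch size", {
  img <- synth_image("random", 28, 28, seed = 4)
  for (p in c(2, 4, 7, 14, 28)) {
    f <- gcfe(img, p, "grid2d")
    expect_equal(f$n_patches * f$n_nodes, 784)
    expect_equal(length(f$features), 2 * 28 * 28)
  }
})

test_that("1d and 2d layouts rearrange the same multiset of values", {
  img <- synth_image("random", 28, 28, seed = 6)
  f <- gcfe(img, 2, "grid2d")
  v1 <- gcfe_layout_1d(f)
  expect_length(v1, 1568)
  # interleaved: patch 1's radii first, then its centers
  expect_equal(v1[1:4], f$radii[1, ])
  expect_equal(v1[5:8], f$centers[1, ])
  plane <- gcfe_layout_2d(f)
  expect_equal(dim(plane), c(2L, 784L, 1L))
  expect_equal(plane[1, 1:4, 1], f$radii[1, ])
  expect_equal(plane[2, , 1], c(t(f$centers)))
  expect_setequal(v1, c(plane))
  blocked <- gcfe_layout_1d(f, order = "blocked")
  expect_equal(blocked, c(plane[1, , 1], plane[2, , 1]))
  # whole-image patching gives the same plane width
  expect_equal(dim(gcfe_layout_2d(gcfe(img, 28, "grid2d"))), c(2L, 784L, 1L))
})

test_that("feature sums recover edge totals: sum(C) = 2|E|, sum(R) = sum(A)", {
  for (ci in seq_len(nrow(graph_cases))) {
    patch <- random_patch(graph_cases$p[ci], seed = 500 + ci)
    g <- build_case_graph(patch, graph_cases$type[ci])
    l <- mwl(g)
    expect_equal(sum(gershgorin_centers(l)), 2 * nrow(g$edges))
    expect_equal(sum(gershgorin_radii(l)), sum(weighted_adjacency(g)))
  }
})

test_that("node relabeling permutes (radius, center) pairs identically", {
  for (seed in 1:5) {
    patch <- random_patch(4, seed = 600 + seed)
    l <- mwl(build_pairwise(patch))
    perm <- withr::with_seed(seed, sample(nrow(l)))
    lp <- l[perm, perm]
    expect_equal(gershgorin_radii(lp), gershgorin_radii(l)[perm])
    expect_equal(gershgorin_centers(lp), gershgorin_centers(l)[perm])
  }
})

test_that("extraction is deterministic and its methods run", {
  img <- synth_image("random", 8, 8, seed = 3)
  f1 <- gcfe(img, 4, "knn", knn_k = 4)
  f2 <- gcfe(img, 4, "knn", knn_k = 4)
  expect_identical(f1$features, f2$features)
  expect_equal(f1$knn_k, 4)  # K defaults to patch size when omitted
  expect_identical(gcfe(img, 4, "knn")$features, f1$features)
  expect_output(print(f1), "knn graph, k = 4")
  expect_output(summary(f1), "dominance margin")
  m <- as.matrix(f1)
  expect_equal(dim(m), c(64L, 2L))
  expect_true(all(m[, "center"] >= m[, "radius"]))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(f1, patches = 1:2))
})

test_that("RGB input is reduced to luminance before graph construction", {
  rgb <- array(0L, c(4, 4, 3))
  rgb[, , 1] <- synth_image("random", 4, 4, seed = 12)
  rgb[, , 2] <- synth_image("random", 4, 4, seed = 13)
  rgb[, , 3] <- synth_image("random", 4, 4, seed = 14)
  f_rgb <- gcfe(rgb, 2, "pairwise")
  f_gray <- gcfe(to_grayscale(rgb), 2, "pairwise")
  expect_identical(f_rgb$features, f_gray$features)
  expect_error(gcfe(rgb, 2, "pairwise", grayscale = FALSE), "grayscale")
})
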