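test_that("layer-wise parameter formulas are exact", {
  spec <- build_gcfe_2d_spec(784, 47)
  params <- attr(propagate_shapes(spec), "params")
  expect_equal(params[1], 1 * 3 * 1 * 32 + 32)      # first conv: 128
  expect_equal(params[c(2, 4, 6, 7)], rep(0, 4))    # pools and flatten free
  expect_equal(params[8], 6272 * 512 + 512)         # 3,211,776
  expect_equal(params[9], 512 * 512 + 512)
  expect_equal(params[11], 512 * 47 + 47)
})

test_that("GC-feature 2D spec propagates shapes by width halvings only", {
  spec <- build_gcfe_2d_spec(784, 47)
  shapes <- propagate_shapes(spec)
  expect_equal(shapes[[2]], c(2, 392, 32))
  expect_equal(shapes[[4]], c(2, 196, 32))
  expect_equal(shapes[[6]], c(2, 98, 32))
  expect_equal(shapes[[7]], 2 * 98 * 32)  # flatten width 6272
  expect_equal(count_parameters(spec), 3504879)
  # exactly three conv layers of 32 filters
  convs <- Filter(function(l) l$kind == "conv", spec$layers)
  expect_length(convs, 3)
  expect_true(all(vapply(convs, `[[`, integer(1), "filters") == 32L))
})

test_that("GC-feature parameter count is invariant to patch size", {
  # same image, any divisor patching: P * N = 784 always
  counts <- vapply(c(2, 4, 7, 14, 28), function(p) {
    count_parameters(build_gcfe_2d_spec(784, 47))
  }, numeric(1))
  expect_true(all(counts == counts[1]))
  expect_error(build_gcfe_2d_spec(4, 47), ">= 8")
})

test_that("stacked-Laplacian spec reproduces the published counts", {
  # patch 14 on 28x28: 4 Laplacians of 196x196 stacked -> (784, 196, 1)
  spec14 <- build_laplacian_2d_spec(4, 196, 47)
  shapes <- propagate_shapes(spec14)
  expect_equal(shapes[[6]], c(98, 24, 32))  # floor(49/2) = 24
  expect_equal(shapes[[7]], 98 * 24 * 32)   # 75,264
  expect_equal(count_parameters(spec14), 38841263)
  # patch 28: one 784x784 Laplacian
  spec28 <- build_laplacian_2d_spec(1, 784, 47)
  expect_equal(propagate_shapes(spec28)[[7]], 98 * 98 * 32)
  expect_equal(count_parameters(spec28), 157658031)
  # output layer follows the class count
  expect_equal(tail(propagate_shapes(build_laplacian_2d_spec(4, 196, 10)),
                    1)[[1]], 10)
})

test_that("a pooled dimension collapsing to zero is rejected", {
  # patch 2 on 28x28: widths 4 -> 2 -> 1 -> 0
  expect_error(build_laplacian_2d_spec(196, 4, 47), "collapsed to zero")
})

test_that("count_parameters is additive over layers", {
  spec <- build_laplacian_2d_spec(4, 196, 47)
  expect_equal(count_parameters(spec),
               sum(attr(propagate_shapes(spec), "params")))
  expect_output(print(spec), "38,841,263")
})

test_that("70/15/15 split of 1000 samples gives 700/150/150", {
  idx <- split_indices(1000, c(0.7, 0.15, 0.15))
  expect_equal(lengths(idx), c("1" = 700, "2" = 150, "3" = 150))
  expect_setequal(unlist(idx), 1:1000)
  # seeded permutation is reproducible and disjoint
  a <- split_indices(100, seed = 5)
  b <- split_indices(100, seed = 5)
  expect_identical(a, b)
  expect_length(intersect(a[[1]], a[[2]]), 0)
})

test_that("training without a deep-learning backend raises a capability error", {
  spec <- build_gcfe_2d_spec(784, 2)
  expect_error(
    train_and_evaluate(spec, matrix(0, 4, 1568), c(0, 1, 0, 1)),
    class = "gcfe_capability_error"
  )
})
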