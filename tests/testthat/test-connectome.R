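test_that("functional connectivity is the Pearson correlation matrix", {
  set.seed(8)
  a <- rnorm(30)
  ts <- cbind(a, 2 * a + 5, -a, rnorm(30))
  fc <- build_fc(ts)
  expect_equal(fc[1, 2], 1, tolerance = 1e-12)   # affine rescaling invariance
  expect_equal(fc[1, 3], -1, tolerance = 1e-12)
  expect_equal(diag(fc), rep(0, 4), ignore_attr = TRUE)

  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  fc2 <- build_fc(cbind(x, y))
  expect_equal(fc2[1, 2], 6.5 / sqrt(5 * 8.75), tolerance = 1e-12)

  expect_error(build_fc(ts[1:2, ]), "3 time points")
})

test_that("zero-variance nodes get zero rows with a warning", {
  set.seed(9)
  ts <- cbind(rnorm(20), rep(1, 20), rnorm(20))
  expect_warning(fc <- build_fc(ts), "Zero-variance")
  expect_equal(fc[2, ], rep(0, 3), ignore_attr = TRUE)
  expect_equal(fc[, 2], rep(0, 3), ignore_attr = TRUE)
})

test_that("structural connectivity is the elementwise FA x FN product", {
  fa <- wadj(3, c(1, 2, 2, 3), c(0.5, 0.8))
  fn <- wadj(3, c(1, 2, 2, 3), c(10, 0))
  fn[2, 3] <- fn[3, 2] <- 0
  expect_warning(sc <- build_sc(fa, fn), "zero patterns")
  expect_equal(sc[1, 2], 5)
  expect_equal(sc[2, 3], 0)
  expect_true(isSymmetric(sc))
  expect_error(build_sc(fa, matrix(0, 4, 4)), "shape")
})

test_that("the default sparsity grid has 41 values from 0.05 to 0.45", {
  g <- sparsity_grid()
  expect_length(g, 41)
  expect_equal(g[1], 0.05)
  expect_equal(g[41], 0.45, tolerance = 1e-9)
  expect_equal(sparsity_grid(0.1, 0.1, 0.01), 0.1)
  expect_error(sparsity_grid(0.1, 0.2, 0.5), "larger than the grid range")
})

test_that("proportional thresholding retains the round-half-up edge count", {
  set.seed(10)
  m <- matrix(0, 90, 90)
  ut <- upper.tri(m)
  m[ut] <- runif(sum(ut))
  m <- m + t(m)
  expect_equal(threshold_proportional(m, 0.05)$retained_edges, 200)
  expect_equal(threshold_proportional(m, 0.10)$retained_edges, 401)

  # sparsity beyond the available edges leaves the network unchanged
  sp <- rand_wgraph(20, 0.2, pow2 = FALSE)
  n_avail <- sum(sp[upper.tri(sp)] > 0)
  tn <- threshold_proportional(sp, 0.9)
  expect_equal(tn$retained_edges, n_avail)
  expect_equal(tn$weights, sp, ignore_attr = TRUE)

  expect_error(threshold_proportional(rand_wgraph(5, 0.9), 0.01),
               "Degenerate sparsity")
})

test_that("thresholding nests monotonically and never alters weights", {
  set.seed(11)
  m <- rand_wgraph(30, 0.8, pow2 = FALSE)
  grid <- seq(0.05, 0.45, 0.05)
  prev <- NULL
  for (s in grid) {
    tn <- threshold_proportional(m, s)
    kept <- tn$weights[upper.tri(tn$weights)] > 0
    if (!is.null(prev)) expect_true(all(kept[prev]))
    prev <- kept
    nz <- tn$weights != 0
    expect_equal(tn$weights[nz], m[nz])
  }
})

test_that("negative-weight policies differ as documented", {
  m <- wadj(4, c(1, 2, 1, 3, 2, 3, 3, 4), c(0.9, -0.8, 0.3, 0.1))
  z <- threshold_proportional(m, 0.35)  # k = floor(2.1+0.5) = 2
  expect_equal(sort(z$weights[upper.tri(z$weights) & z$weights != 0]),
               c(0.3, 0.9))
  a <- threshold_proportional(m, 0.35, policy = "absolute")
  expect_equal(sort(a$weights[upper.tri(a$weights) & a$weights != 0]),
               c(0.8, 0.9))  # |r| ranked and retained as |r|
})
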