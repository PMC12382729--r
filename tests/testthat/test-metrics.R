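test_that("hand-computable graphs give the expected metric values", {
  tri <- wadj(3, c(1, 2, 2, 3, 1, 3))
  g <- compute_global(tri)
  expect_equal(g$Cp, 1)
  expect_equal(g$Lp, 1)
  expect_equal(g$Eg, 1)
  expect_equal(g$Eloc, 1)

  path3 <- wadj(3, c(1, 2, 2, 3))
  gp <- compute_global(path3)
  expect_equal(gp$Eg, (1 + 1 + 0.5) / 3, tolerance = 1e-12)
  expect_equal(gp$Lp, (1 + 1 + 2) / 3, tolerance = 1e-12)

  d <- shortest_path_lengths(path3)
  expect_equal(d[1, 3], 2)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(unname(shortest_path_lengths(tri)[upper.tri(tri)]),
               rep(1, 3))

  nod <- compute_nodal(path3)
  expect_equal(nod$Bc, c(0, 1, 0))

  star <- wadj(4, c(1, 2, 1, 3, 1, 4))
  ns <- compute_nodal(star)
  expect_equal(ns$Dc[1], 3)
  expect_equal(ns$NCp[1], 0)
})

test_that("strength satisfies the handshake identity", {
  set.seed(12)
  w <- rand_wgraph(15, 0.4, pow2 = FALSE)
  nod <- compute_nodal(w)
  expect_equal(sum(nod$Dc), 2 * sum(w[upper.tri(w)]), tolerance = 1e-10)
})

test_that("distances match a Floyd-Warshall oracle on random graphs", {
  set.seed(13)
  for (rep in 1:10) {
    w <- rand_wgraph(10, 0.5, pow2 = rep %% 2 == 0)
    expect_lt(max(abs(shortest_path_lengths(w) - oracle_fw(w)),
                  na.rm = TRUE), 1e-12)
  }
})

test_that("all metrics match brute-force references on random graphs", {
  set.seed(14)
  for (rep in 1:50) {
    n <- sample(5:12, 1)
    w <- rand_wgraph(n, runif(1, 0.3, 0.8), pow2 = runif(1) < 0.6)
    if (all(w == 0)) next
    og <- oracle_global(w)
    g <- suppressWarnings(compute_global(w))
    expect_equal(g$Cp, og$Cp, tolerance = 1e-10)
    expect_equal(g$Lp, og$Lp, tolerance = 1e-10)
    expect_equal(g$Eg, og$Eg, tolerance = 1e-10)
    expect_equal(g$Eloc, og$Eloc, tolerance = 1e-10)
    on <- oracle_nodal(w)
    nod <- suppressWarnings(compute_nodal(w))
    expect_equal(nod$Dc, unname(on$Dc), tolerance = 1e-10)
    expect_equal(nod$Bc, on$Bc, tolerance = 1e-10)
    expect_equal(nod$Ne, on$Ne, tolerance = 1e-10)
    expect_equal(nod$Nle, on$Nle, tolerance = 1e-10)
    expect_equal(nod$NCp, on$NCp, tolerance = 1e-10)
  }
})

test_that("metrics scale correctly under global weight rescaling", {
  set.seed(15)
  w <- rand_wgraph(12, 0.5, pow2 = FALSE)
  c0 <- 3.7
  g1 <- compute_global(w)
  g2 <- compute_global(c0 * w)
  expect_equal(g2$Cp, g1$Cp, tolerance = 1e-12)     # max-normalized
  expect_equal(g2$Lp, g1$Lp / c0, tolerance = 1e-12)
  expect_equal(g2$Eg, g1$Eg * c0, tolerance = 1e-12)
})

test_that("degenerate networks are handled explicitly", {
  empty <- matrix(0, 4, 4)
  expect_warning(g <- compute_global(empty), "Empty edge set")
  expect_equal(unlist(g[, c("Cp", "Lp", "Eg", "Eloc")]),
               c(Cp = 0, Lp = 0, Eg = 0, Eloc = 0))
  expect_warning(nod <- compute_nodal(empty), "Empty edge set")
  expect_equal(nod$Dc, rep(0, 4))
  neg <- wadj(3, c(1, 2), -1)
  expect_error(shortest_path_lengths(neg), "Negative")
})

test_that("AUC integration matches closed forms", {
  grid <- sparsity_grid()
  expect_equal(integrate_auc(rep(0.5, 41), grid), 0.2, tolerance = 1e-12)
  expect_equal(integrate_auc(grid, grid), 0.1, tolerance = 1e-12)
  expect_equal(integrate_auc(c(2, 4), c(0.1, 0.2)), 3 * 0.1,
               tolerance = 1e-12)
  expect_equal(integrate_auc(rep(0.5, 41), grid, rule = "rectangle"),
               0.01 * sum(rep(0.5, 41)), tolerance = 1e-12)
  expect_error(integrate_auc(c(1, NaN, 3), c(0.1, 0.2, 0.3)),
               "sparsity 0.2")
  expect_error(integrate_auc(1:3, 1:2), "same length")
})

test_that("metric curves cache saturated thresholds consistently", {
  set.seed(16)
  w <- rand_wgraph(20, 0.15, pow2 = FALSE)
  grid <- seq(0.05, 0.45, 0.05)
  cur <- metric_curves(w, grid = grid, metrics = c("Lp", "Eg"))
  expect_equal(nrow(cur), 2 * length(grid))
  # beyond saturation the curve is flat at the full-network value
  full <- compute_global(w, metrics = c("Lp", "Eg"))
  last <- cur[cur$sparsity == 0.45, ]
  expect_equal(last$value[last$metric == "Lp"], full$Lp, tolerance = 1e-12)
  expect_equal(last$value[last$metric == "Eg"], full$Eg, tolerance = 1e-12)
  au <- auc_table(cur)
  expect_equal(nrow(au), 2)
  expect_true(all(is.finite(au$auc)))
})
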