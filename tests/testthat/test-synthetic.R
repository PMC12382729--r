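test_that("the backbone template hits the rounded edge count and density", {
  set.seed(20)
  tpl <- make_group_template(cohort_config())
  expect_equal(nrow(tpl$edges), floor(0.15 * 4005 + 0.5))  # 601
  expect_equal(nrow(tpl$edges), 601)
  expect_true(all(tpl$fa >= 0.2 & tpl$fa <= 0.9))
  expect_true(all(tpl$fn >= 1 & tpl$fn == round(tpl$fn)))

  # rewire_prob 0 keeps the modular fill order: within-module pairs are
  # saturated before any between-module edge is placed
  set.seed(21)
  tpl0 <- make_group_template(cohort_config(rewire_prob = 0,
                                            backbone_density = 0.2))
  mods <- tpl0$module
  within <- mods[tpl0$edges[, 1]] == mods[tpl0$edges[, 2]]
  n_within_pairs <- sum(outer(mods, mods, "==")[upper.tri(diag(90))])
  expect_equal(sum(within), n_within_pairs)  # all 630 within-pairs present
  expect_equal(nrow(tpl0$edges), floor(0.2 * 4005 + 0.5))

  # purely within-module edges can never connect the graph: the generator
  # must give up explicitly rather than loop forever
  set.seed(211)
  expect_error(
    make_group_template(cohort_config(rewire_prob = 0,
                                      backbone_density = 0.14)),
    "connected backbone"
  )

  # single module degenerates to an unstructured template at the density
  set.seed(22)
  tpl1 <- make_group_template(cohort_config(n_modules = 1))
  expect_equal(nrow(tpl1$edges), 601)
})

test_that("subject matrices respect FA bounds, integer FN, zero patterns", {
  set.seed(23)
  cfg <- cohort_config()
  tpl <- make_group_template(cfg)
  for (grp in c("HC", "HS")) {
    sub <- sample_subject_sc(tpl, grp, cfg)
    expect_true(all(sub$fa >= 0 & sub$fa <= 1))
    expect_true(all(sub$fn >= 0 & sub$fn == round(sub$fn)))
    expect_identical(sub$fa == 0, sub$fn == 0)
    expect_true(all(rowSums(sub$fn) > 0))  # no isolated nodes
  }

  cfg5 <- cohort_config(fa_range = c(0.5, 0.5))
  tpl5 <- make_group_template(cfg5)
  sub5 <- sample_subject_sc(tpl5, "HC", cfg5)
  expect_true(all(sub5$fa[sub5$fa != 0] == 0.5))
})

test_that("hub attenuation lowers affected-node strength in patients", {
  set.seed(24)
  cfg <- cohort_config()
  tpl <- make_group_template(cfg)
  aff <- cfg$affected_nodes
  str_hs <- str_hc <- numeric(100)
  for (i in 1:100) {
    hs <- sample_subject_sc(tpl, "HS", cfg)
    hc <- sample_subject_sc(tpl, "HC", cfg)
    str_hs[i] <- mean(rowSums(build_sc(hs$fa, hs$fn))[aff])
    str_hc[i] <- mean(rowSums(build_sc(hc$fa, hc$fn))[aff])
  }
  expect_lt(mean(str_hs), mean(str_hc))
  expect_gt(mean(str_hs < mean(str_hc)), 0.9)  # Monte-Carlo sign check
})

test_that("null configuration makes the groups exchangeable draws", {
  set.seed(25)
  cfg <- null_cohort_config(seed = 1)
  tpl <- make_group_template(cfg)
  set.seed(99)
  hs <- sample_subject_sc(tpl, "HS", cfg)
  set.seed(99)
  hc <- sample_subject_sc(tpl, "HC", cfg)
  expect_identical(hs, hc)  # identical sampling path when effects are off
})

test_that("simulated time series are coupled to the structural weights", {
  cfg <- cohort_config(fc_noise_sd = 0)
  # zero structure -> near-zero mean off-diagonal correlation
  set.seed(26)
  zero_sc <- matrix(0, 20, 20)
  mean_r <- replicate(100, {
    ts <- simulate_timeseries(zero_sc, 190, cfg)
    fc <- build_fc(ts)
    mean(fc[upper.tri(fc)])
  })
  expect_lt(abs(mean(mean_r)), 0.05)

  # the strongest structural edge carries the strongest expected correlation
  set.seed(27)
  sc <- rand_wgraph(10, 0.5, pow2 = FALSE)
  strongest <- which(sc == max(sc), arr.ind = TRUE)[1, ]
  ts <- simulate_timeseries(sc, 20000, cfg)
  fc <- build_fc(ts)
  top <- which(fc == max(fc[upper.tri(fc)]), arr.ind = TRUE)[1, ]
  expect_setequal(unname(top), unname(strongest))

  # determinism under a fixed seed
  set.seed(28); a <- simulate_timeseries(sc, 50, cfg)
  set.seed(28); b <- simulate_timeseries(sc, 50, cfg)
  expect_identical(a, b)

  expect_error(simulate_timeseries(matrix(c(0, -1, -1, 0), 2), 30, cfg),
               "non-negative")
})

test_that("clinical scores carry the configured metric links", {
  sm <- tibble::tibble(
    subject_id = sprintf("HS%02d", 1:20), group = "HS",
    lp_auc = seq(0.1, 0.3, length.out = 20),
    eg_auc = seq(5, 3, length.out = 20),
    ne_probe_auc = seq(2, 6, length.out = 20)
  )
  noiseless <- cohort_config(scale_link = list(
    wisc = c(center = 73.64, slope = 8, noise = 0),
    wms = c(center = 75.08, slope = 7, noise = 0),
    adhd = c(center = 24.61, slope = 5.5, noise = 0)
  ))
  out <- assign_clinical(sm, noiseless)
  expect_equal(cor(out$wisc, out$lp_auc), -1, tolerance = 1e-12)
  expect_equal(cor(out$wms, out$ne_probe_auc), 1, tolerance = 1e-12)
  expect_equal(cor(out$adhd, out$lp_auc), 1, tolerance = 1e-12)

  set.seed(29)
  zero_slope <- assign_clinical(sm, null_cohort_config(1))
  expect_lt(abs(cor(zero_slope$wisc, zero_slope$lp_auc)), 0.6)
})

test_that("patient-group WISC means sit near the configured center", {
  means <- numeric(5)
  for (i in 1:5) {
    coh <- generate_cohort(cohort_config(seed = 300 + i),
                           timeseries = FALSE, clinical = TRUE)
    means[i] <- mean(coh$manifest$wisc[coh$manifest$group == "HS"])
  }
  expect_true(all(abs(means - 73.64) < 10))
})

test_that("cohorts have the right shape, demographics and determinism", {
  coh <- default_sc_cohort()
  man <- coh$manifest
  expect_equal(nrow(man), 72)
  expect_equal(as.vector(table(man$group)), c(36, 36))
  expect_true(all(man$age >= 6 & man$age <= 13))
  expect_identical(man$sex[man$group == "HS"], man$sex[man$group == "HC"])
  expect_true(all(man$duration[man$group == "HS"] >= 0.5))
  expect_true(all(is.na(man$duration[man$group == "HC"])))
  expect_true(all(is.na(man$wisc[man$group == "HC"])))

  a <- generate_cohort(cohort_config(n_per_group = 3, seed = 7),
                       timeseries = FALSE, clinical = FALSE)
  b <- generate_cohort(cohort_config(n_per_group = 3, seed = 7),
                       timeseries = FALSE, clinical = FALSE)
  expect_equal(nrow(a$manifest), 6)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$subjects[[1]]$sc, b$subjects[[1]]$sc)
})

test_that("the default patient effect shifts path length and efficiency", {
  coh <- default_sc_cohort()
  m <- coh$metrics
  hs <- m[m$group == "HS", ]; hc <- m[m$group == "HC", ]
  expect_gt(mean(hs$lp_auc), mean(hc$lp_auc))
  expect_lt(mean(hs$eg_auc), mean(hc$eg_auc))
  expect_lt(mean(hs$ne_probe_auc), mean(hc$ne_probe_auc))
})
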