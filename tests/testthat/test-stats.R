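test_that("the KS normality gate is calibrated and powered", {
  set.seed(34)
  p_norm <- replicate(100, ks_normality(rnorm(500))$p.value)
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_exp <- replicate(50, ks_normality(rexp(500))$p.value)
  expect_gte(mean(p_exp < 0.05), 0.95)
  expect_error(ks_normality(rep(1, 10)), "Zero variance")
  expect_error(ks_normality(c(1, 2)), "n >= 5")
})

test_that("two-group comparisons use the documented branches", {
  x <- c(1.1, 2.2, 3.3, 4.4, 5.5)
  same <- compare_continuous(x, x, normal = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  shifted <- compare_continuous(x + 100, x, normal = TRUE)
  expect_lt(shifted$p.value, 1e-6)

  mw <- compare_continuous(c(1, 2, 3), c(4, 5, 6), normal = FALSE)
  expect_equal(mw$statistic, 0)       # U = 0
  expect_equal(mw$p.value, 0.1)       # exact two-sided enumeration
  expect_match(mw$method, "Mann-Whitney")
  expect_error(compare_continuous(1, c(1, 2)), "at least 2")
})

test_that("chi-square on 2x2 counts reproduces the closed-form statistic", {
  res <- chi_square_counts(matrix(c(24, 20, 12, 16), 2))
  expect_equal(res$statistic,
               72 * (24 * 16 - 12 * 20)^2 / (36 * 36 * 44 * 28),
               tolerance = 1e-12)
  expect_equal(round(res$p.value, 3), 0.334)

  even <- chi_square_counts(matrix(10, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p.value, 1)

  diag60 <- chi_square_counts(matrix(c(30, 0, 0, 30), 2))
  expect_equal(diag60$statistic, 60, tolerance = 1e-12)
  expect_lt(diag60$p.value, 1e-10)

  expect_error(chi_square_counts(matrix(c(5, 5, 0, 0), 2, byrow = TRUE)),
               "margin")
})

test_that("a covariate-free GLM contrast equals the pooled t-test", {
  set.seed(35)
  d <- tibble::tibble(
    value = rnorm(40),
    group = factor(rep(c("HC", "HS"), 20), levels = c("HC", "HS"))
  )
  glm_res <- glm_contrast(d, covariates = character(0))
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  expect_equal(glm_res$p.value, tt$p.value, tolerance = 1e-12)
  expect_equal(glm_res$estimate,
               mean(d$value[d$group == "HS"]) - mean(d$value[d$group == "HC"]),
               tolerance = 1e-12)

  d2 <- d
  d2$age <- rnorm(40); d2$age2 <- d2$age * 2
  expect_error(glm_contrast(d2, covariates = c("age", "age2")), "Collinear")
})

test_that("GLM group p-values are uniform under a pure covariate effect", {
  set.seed(36)
  pvals <- replicate(2000, {
    age <- runif(40, 6, 13)
    d <- tibble::tibble(
      value = 2 * age + rnorm(40),
      group = factor(sample(rep(c("HC", "HS"), 20)), levels = c("HC", "HS")),
      age = age,
      sex = factor(sample(c("M", "F"), 40, TRUE), levels = c("F", "M")),
      duration = ifelse(runif(40) < 0.5, NA, runif(40, 1, 10))
    )
    glm_contrast(d)$p.value
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("Bonferroni thresholds are reported to 7 decimals", {
  expect_identical(bonferroni_threshold(0.05, 90), 0.0005556)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("the permutation test has the documented p-value structure", {
  set.seed(37)
  # groups separated by many pooled SDs -> minimum attainable p
  x <- c(rnorm(10), rnorm(10) + 50)
  lab <- rep(c("a", "b"), each = 10)
  res <- permutation_test(x, lab, n_perm = 199, seed = 1)
  expect_equal(res$p.value, 1 / 200)

  # zero observed difference -> p = 1
  res0 <- permutation_test(c(1, 2, 2, 1), c("a", "a", "b", "b"),
                           n_perm = 99, seed = 2)
  expect_equal(res0$estimate, 0)
  expect_equal(res0$p.value, 1)

  expect_error(permutation_test(1:4, rep("a", 4), 10), "two groups")
})

test_that("permutation p-values are uniform under exchangeability", {
  set.seed(38)
  pvals <- replicate(200, {
    x <- rnorm(30)
    lab <- sample(rep(c("a", "b"), 15))
    permutation_test(x, lab, n_perm = 199)$p.value
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("partial correlation reduces to Pearson and removes covariates", {
  set.seed(39)
  x <- rnorm(30); y <- x + rnorm(30)
  pc <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$estimate, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p.value, ct$p.value, tolerance = 1e-12)

  z <- rnorm(30)
  y2 <- x + 3 * z
  pc2 <- partial_correlation(x, y2, covariates = data.frame(z = z))
  expect_equal(pc2$estimate, 1, tolerance = 1e-10)

  expect_error(partial_correlation(x, y, data.frame(z = z, z2 = z)),
               "Collinear")
})

test_that("group contrasts apply Bonferroni within 90-node families", {
  set.seed(40)
  man <- make_manifest(20)
  auc_nodal <- tidyr::expand_grid(
    subject_id = man$subject_id, network = "SCN", metric = "Ne",
    node = 1:90
  )
  auc_nodal$auc <- rnorm(nrow(auc_nodal))
  res <- group_contrasts(auc_nodal, man)
  expect_equal(nrow(res), 90)
  expect_true(all(res$alpha_adjusted == 0.0005556))
  expect_true(all(res$correction == "bonferroni"))
  expect_identical(res$significant, res$p.value < 0.0005556)

  gl <- glance(res)
  expect_equal(gl$n_tests, 90)
  expect_s3_class(tidy(res), "tbl_df")
})

test_that("demographic tables summarize age, sex and duration", {
  set.seed(41)
  man <- make_manifest(36)
  demo <- demographic_table(man)
  expect_equal(nrow(demo), 3)
  expect_true(all(c("characteristic", "p.value") %in% names(demo)))
  expect_true(is.na(demo$p.value[3]))
})

test_that("clinical partial correlations recover a planted association", {
  set.seed(42)
  man <- make_manifest(30)
  hs_ids <- man$subject_id[man$group == "HS"]
  auc <- tibble::tibble(
    subject_id = rep(man$subject_id, 2),
    network = rep(c("FCN", "SCN"), each = nrow(man)),
    metric = "Lp",
    auc = rnorm(2 * nrow(man))
  )
  # plant a strong negative WISC-Lp link in the FCN rows
  fcn_hs <- auc$network == "FCN" & auc$subject_id %in% hs_ids
  man$wisc[match(auc$subject_id[fcn_hs], man$subject_id)] <-
    73.64 - 10 * auc$auc[fcn_hs] + rnorm(sum(fcn_hs), 0, 0.5)
  res <- clinical_correlations(auc, man)
  row <- res[res$scale == "wisc" & res$network == "FCN", ]
  expect_lt(row$r, -0.9)
  expect_true(row$significant)
})
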