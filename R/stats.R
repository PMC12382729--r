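stat_row <- function(method, estimate = NA_real_, statistic = NA_real_,
                     p.value = NA_real_, n = NA_integer_, df = NA_real_,
                     correction = "none", alpha_adjusted = NA_real_) {
  out <- tibble(method = method, estimate = estimate, statistic = statistic,
                p.value = p.value, n = as.integer(n), df = df,
                correction = correction, alpha_adjusted = alpha_adjusted)
  class(out) <- c("stat_result", class(out))
  out
}

#' @export
tidy.stat_result <- function(x, ...) as_tibble(unclass_tbl(x))

#' @export
glance.stat_result <- function(x, ...) {
  as_tibble(unclass_tbl(x))[, c("method", "statistic", "p.value")]
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("stat_result", "ns_contrasts"))
  x
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the values against a normal distribution with
#' the sample mean and standard deviation, with the p-value taken from the
#' asymptotic KS distribution. Because the reference parameters are
#' estimated, this is an approximation to a Lilliefors-corrected test and is
#' mildly conservative; it is used only to gate the t versus Mann-Whitney
#' branch.
#'
#' @param values Numeric vector, n >= 5, non-degenerate.
#' @return A `stat_result` tibble.
#' @export
ks_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5) abort("Normality check needs n >= 5.")
  s <- stats::sd(values)
  if (s == 0) abort("Zero variance: normality check undefined.")
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s)
  )
  stat_row("Kolmogorov-Smirnov normality", statistic = unname(kt$statistic),
           p.value = kt$p.value, n = length(values))
}

#' Two-group comparison of a continuous variable
#'
#' Pooled-variance two-sample t-test when both groups pass the KS normality
#' gate (or `normal = TRUE`), otherwise a Mann-Whitney U test (exact for
#' small tie-free samples, normal approximation with tie correction
#' otherwise). Two-sided throughout.
#'
#' @param x,y Numeric vectors for the two groups (n >= 2 each).
#' @param normal Optional logical override of the normality gate.
#' @param alpha Alpha for the normality gate.
#' @return A `stat_result` tibble; `estimate` is the mean (t branch) or
#'   median (U branch) difference `x - y`.
#' @export
compare_continuous <- function(x, y, normal = NULL, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("Both groups need at least 2 observations.")
  }
  if (is.null(normal)) {
    normal <- tryCatch(
      ks_normality(x)$p.value > alpha && ks_normality(y)$p.value > alpha,
      error = function(e) FALSE
    )
  }
  if (isTRUE(normal)) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    stat_row("Two-sample t (pooled variance)",
             estimate = mean(x) - mean(y),
             statistic = unname(tt$statistic), p.value = tt$p.value,
             n = length(x) + length(y), df = unname(tt$parameter))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    stat_row("Mann-Whitney U",
             estimate = stats::median(x) - stats::median(y),
             statistic = unname(wt$statistic), p.value = wt$p.value,
             n = length(x) + length(y))
  }
}

#' Pearson chi-square test on a 2x2 count table
#'
#' No continuity correction (df = 1), matching the convention needed to
#' reproduce demographic sex-ratio tests from printed counts.
#'
#' @param table2x2 2x2 matrix of non-negative integer counts.
#' @return A `stat_result` tibble.
#' @export
#' @examples
#' chi_square_counts(matrix(c(24, 20, 12, 16), 2))  # p = 0.334
chi_square_counts <- function(table2x2) {
  tab <- as.matrix(table2x2)
  if (!all(dim(tab) == c(2, 2))) abort("Expected a 2x2 count table.")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("Counts must be non-negative integers.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Zero margin: chi-square undefined.")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat_row("Pearson chi-square (no continuity correction)",
           statistic = unname(ct$statistic), p.value = ct$p.value,
           n = sum(tab), df = unname(ct$parameter))
}

#' Covariate-adjusted group contrast via a general linear model
#'
#' Fits `value ~ group + covariates` by ordinary least squares and reports
#' the group coefficient (patients coded 1, controls 0, so positive estimates
#' mean patients > controls), its t statistic and two-sided p-value. Disease
#' duration is 0 for controls by convention, so the covariate acts as a
#' within-patient adjustment.
#'
#' @param data Tibble with columns `value`, `group` (factor HC/HS) and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names (subset of
#'   the data's columns); `sex` is coded 0/1 internally, missing `duration`
#'   becomes 0.
#' @return A `stat_result` tibble.
#' @export
glm_contrast <- function(data, covariates = c("age", "sex", "duration")) {
  df <- as_tibble(data)
  if (!all(c("value", "group") %in% names(df))) {
    abort("`data` needs `value` and `group` columns.")
  }
  missing_cov <- setdiff(covariates, names(df))
  if (length(missing_cov) > 0) {
    abort(paste0("Missing covariate column(s): ",
                 paste(missing_cov, collapse = ", ")))
  }
  design <- data.frame(y = df$value, group = as.integer(df$group == "HS"))
  for (cv in covariates) {
    v <- df[[cv]]
    if (cv == "sex" || is.factor(v)) v <- as.integer(v == levels(factor(v))[1])
    if (cv == "duration") v <- ifelse(is.na(v), 0, v)
    design[[cv]] <- as.numeric(v)
  }
  if (nrow(design) <= ncol(design) + 1) {
    abort("Too few observations for the requested covariates.")
  }
  fit <- stats::lm(y ~ ., data = design)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Collinear design; aliased term(s): ",
                 paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  row <- sm["group", ]
  stat_row("GLM group contrast (OLS)",
           estimate = unname(row["Estimate"]),
           statistic = unname(row["t value"]),
           p.value = unname(row["Pr(>|t|)"]),
           n = nrow(df), df = fit$df.residual)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise alpha.
#' @param m Number of tests in the family (>= 1).
#' @return `alpha / m`, reported to 7 decimals.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 90)  # 0.0005556
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) abort("`m` must be at least 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  round(alpha / m, 7)
}

#' Permutation test for a two-group mean difference
#'
#' The statistic is the difference in group means; group labels are permuted
#' uniformly and the two-sided p-value uses the add-one rule
#' `p = (1 + #(|d_perm| >= |d_obs|)) / (n_perm + 1)`, so p is never 0.
#'
#' @param values Numeric vector.
#' @param labels Two-level grouping vector of the same length.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed.
#' @return A `stat_result` tibble; `estimate` is the observed mean
#'   difference (first level minus second).
#' @export
permutation_test <- function(values, labels, n_perm = 5000, seed = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) abort("Exactly two groups are required.")
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  keep <- !is.na(values)
  values <- values[keep]; labels <- labels[keep]
  g1 <- labels == levels(labels)[1]
  d_obs <- mean(values[g1]) - mean(values[!g1])
  n1 <- sum(g1)
  count <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(values), n1)
    d_perm <- mean(values[idx]) - mean(values[-idx])
    if (abs(d_perm) >= abs(d_obs) - 1e-15) count <- count + 1L
  }
  stat_row("Permutation test (mean difference)",
           estimate = d_obs, statistic = d_obs,
           p.value = (1 + count) / (n_perm + 1), n = length(values))
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on
#' `[intercept, covariates]`; with k covariates the two-sided p-value comes
#' from `t = r * sqrt((n - 2 - k) / (1 - r^2))`. With no covariates this
#' reduces exactly to the plain Pearson correlation test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional matrix/data frame of covariates (rows match
#'   `x`); factors are model-matrix expanded.
#' @return A `stat_result` tibble; `estimate` is the partial r.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  k <- 0L
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    if (nrow(cv) != length(x)) abort("Covariate rows must match `x`.")
    mm <- stats::model.matrix(~ ., data = cv)[, -1, drop = FALSE]
    keep <- complete.cases(x, y, mm)
    x <- x[keep]; y <- y[keep]; mm <- mm[keep, , drop = FALSE]
    k <- ncol(mm)
    design <- cbind(1, mm)
    if (qr(design)$rank < ncol(design)) {
      abort("Collinear covariates in partial correlation.")
    }
    x <- stats::lm.fit(design, x)$residuals
    y <- stats::lm.fit(design, y)$residuals
  } else {
    keep <- complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x)
  if (n <= k + 3) abort("Too few complete observations for the covariates.")
  r <- stats::cor(x, y)
  dfree <- n - 2 - k
  tval <- r * sqrt(dfree / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tval), dfree)
  stat_row("Partial correlation", estimate = r, statistic = tval,
           p.value = p, n = n, df = dfree)
}

#' Demographic comparison table for a cohort manifest
#'
#' Age is compared with the KS-gated t / Mann-Whitney branch, sex with the
#' uncorrected chi-square on the 2x2 table, and patient disease duration is
#' summarized (it has no control counterpart).
#'
#' @param manifest Manifest tibble (see [read_manifest()]).
#' @return Tibble with one row per characteristic.
#' @export
demographic_table <- function(manifest) {
  hs <- manifest %>% filter(.data$group == "HS")
  hc <- manifest %>% filter(.data$group == "HC")
  age <- compare_continuous(hs$age, hc$age)
  sex_tab <- rbind(
    HS = c(M = sum(hs$sex == "M"), F = sum(hs$sex == "F")),
    HC = c(M = sum(hc$sex == "M"), F = sum(hc$sex == "F"))
  )
  sex <- tryCatch(chi_square_counts(sex_tab), error = function(e) {
    stat_row("Pearson chi-square (not testable: zero margin)")
  })
  bind_rows(
    tibble(characteristic = "age", method = age$method,
           hs_mean = mean(hs$age), hc_mean = mean(hc$age),
           statistic = age$statistic, p.value = age$p.value),
    tibble(characteristic = "sex (M/F)",
           method = sex$method,
           hs_mean = sum(hs$sex == "M"), hc_mean = sum(hc$sex == "M"),
           statistic = sex$statistic, p.value = sex$p.value),
    tibble(characteristic = "duration (months, HS only)",
           method = "summary",
           hs_mean = mean(hs$duration, na.rm = TRUE), hc_mean = NA_real_,
           statistic = NA_real_, p.value = NA_real_)
  )
}

#' Covariate-adjusted group contrasts over an AUC table
#'
#' Runs [glm_contrast()] for every (network, metric[, node]) AUC family in
#' the table. Nodal metrics are Bonferroni-corrected within each
#' (network, metric) family of `n_nodes` tests; global metrics use the
#' uncorrected alpha.
#'
#' @param auc Tibble with `subject_id`, `network`, `metric`, `node` (NA for
#'   global) and `auc` columns.
#' @param manifest Manifest tibble supplying group and covariates.
#' @param covariates Covariate names passed to [glm_contrast()].
#' @param alpha Base alpha.
#' @return Tibble of class `ns_contrasts`: one row per test with
#'   `alpha_adjusted` and `significant` columns.
#' @export
group_contrasts <- function(auc, manifest,
                            covariates = c("age", "sex", "duration"),
                            alpha = 0.05) {
  if (!"node" %in% names(auc)) auc$node <- NA_integer_
  joined <- auc %>%
    left_join(manifest, by = "subject_id") %>%
    rename(value = "auc")
  fam <- joined %>%
    group_by(.data$network, .data$metric, .data$node) %>%
    dplyr::group_split()
  rows <- map(fam, function(d) {
    if (nrow(d) <= length(covariates) + 3) {
      warn(paste0("Skipping contrast for ", d$network[1], " ", d$metric[1],
                  ": only ", nrow(d), " subjects with defined AUC."))
      return(NULL)
    }
    res <- glm_contrast(d, covariates = covariates)
    nodal <- !is.na(d$node[1])
    m <- if (nodal) {
      length(unique(auc$node[!is.na(auc$node)]))
    } else 1L
    tibble(
      network = d$network[1], metric = d$metric[1], node = d$node[1],
      estimate = res$estimate, statistic = res$statistic,
      p.value = res$p.value,
      correction = if (nodal) "bonferroni" else "none",
      alpha_adjusted = if (nodal) bonferroni_threshold(alpha, m) else alpha
    )
  })
  out <- bind_rows(rows) %>%
    mutate(significant = .data$p.value < .data$alpha_adjusted)
  class(out) <- c("ns_contrasts", class(out))
  out
}

#' @export
tidy.ns_contrasts <- function(x, ...) as_tibble(unclass_tbl(x))

#' @export
glance.ns_contrasts <- function(x, ...) {
  tibble(n_tests = nrow(x),
         n_significant = sum(x$significant, na.rm = TRUE),
         n_nodal = sum(!is.na(x$node)))
}

#' Partial correlations between clinical scales and network AUC metrics
#'
#' Within the patient group, correlates each clinical scale with each
#' (network, metric) AUC, controlling for age, sex and disease duration.
#'
#' @param auc Global AUC tibble (`subject_id`, `network`, `metric`, `auc`).
#' @param manifest Manifest with scales and covariates.
#' @param scales Scale column names to correlate.
#' @param covariates Covariate column names.
#' @param alpha Significance threshold for the `significant` flag.
#' @return Tibble: `scale`, `network`, `metric`, `r`, `statistic`,
#'   `p.value`, `significant`.
#' @export
clinical_correlations <- function(auc, manifest,
                                  scales = c("wisc", "wms", "adhd"),
                                  covariates = c("age", "sex", "duration"),
                                  alpha = 0.05) {
  hs <- manifest %>% filter(.data$group == "HS")
  if ("node" %in% names(auc)) auc <- auc %>% filter(is.na(.data$node))
  wide <- auc %>%
    left_join(hs, by = "subject_id") %>%
    filter(.data$group == "HS")
  combos <- wide %>% distinct(.data$network, .data$metric)
  rows <- pmap(combos, function(network, metric) {
    d <- wide %>%
      filter(.data$network == !!network, .data$metric == !!metric)
    cov_df <- as.data.frame(d[, covariates, drop = FALSE])
    if ("sex" %in% covariates) cov_df$sex <- as.integer(d$sex == "M")
    bind_rows(lapply(scales, function(sc) {
      res <- if (sum(complete.cases(d$auc, d[[sc]], cov_df)) >
                 length(covariates) + 3) {
        partial_correlation(d$auc, d[[sc]], covariates = cov_df)
      } else {
        warn(paste0("Too few patients for partial correlation of ", sc,
                    " with ", network, " ", metric, "; reported missing."))
        stat_row("Partial correlation (not estimable)")
      }
      tibble(scale = sc, network = network, metric = metric,
             r = res$estimate, statistic = res$statistic,
             p.value = res$p.value)
    }))
  })
  bind_rows(rows) %>% mutate(significant = .data$p.value < alpha)
}
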