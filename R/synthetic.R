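# sample() without the scalar-x surprise
safe_sample <- function(x, size) x[sample.int(length(x), size)]

#' Group-level structural backbone template
#'
#' Draws the modular small-world backbone both groups share: node pairs are
#' split into `n_modules` contiguous blocks, edges are placed within blocks
#' first (between blocks only once the blocks are full), each edge is then
#' rewired with probability `rewire_prob` by moving one endpoint to a uniform
#' random node, and the result must be connected (up to 100 redraws).
#' Template edge attributes — fractional anisotropy uniform over `fa_range`
#' and lognormal fiber counts with mean `fn_scale` — are drawn once and
#' shared by both groups.
#'
#' @param config A [cohort_config()].
#' @return List: `edges` (m x 2 matrix, i < j), `fa`, `fn` (template edge
#'   attributes), `module` (node module index), `n_nodes`.
#' @export
make_group_template <- function(config) {
  n <- config$n_nodes
  n_pairs <- n * (n - 1) / 2
  m <- floor(config$backbone_density * n_pairs + 0.5)
  if (m < n - 1) abort("Backbone density too low to connect the graph.")
  module <- sort(rep(seq_len(config$n_modules), length.out = n))

  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  within <- module[ij[, 1]] == module[ij[, 2]]

  for (attempt in seq_len(100)) {
    w_idx <- which(within)
    b_idx <- which(!within)
    take_w <- min(m, length(w_idx))
    sel <- safe_sample(w_idx, take_w)
    if (take_w < m) sel <- c(sel, safe_sample(b_idx, m - take_w))
    edges <- ij[sel, , drop = FALSE]

    # endpoint rewiring: each edge moves one endpoint with prob rewire_prob
    if (config$rewire_prob > 0) {
      adj <- matrix(FALSE, n, n)
      adj[edges] <- TRUE; adj[edges[, c(2, 1)]] <- TRUE
      do_rewire <- which(runif(m) < config$rewire_prob)
      for (e in do_rewire) {
        i <- edges[e, 1]; j <- edges[e, 2]
        keep <- if (runif(1) < 0.5) i else j
        cand <- which(!adj[keep, ])
        cand <- setdiff(cand, keep)
        if (length(cand) == 0) next
        new <- if (length(cand) == 1) cand else sample(cand, 1)
        adj[i, j] <- adj[j, i] <- FALSE
        adj[keep, new] <- adj[new, keep] <- TRUE
        edges[e, ] <- c(min(keep, new), max(keep, new))
      }
    }

    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, as.vector(t(edges)))
    if (igraph::is_connected(g)) {
      fa <- runif(m, config$fa_range[1], config$fa_range[2])
      sdlog <- 0.6
      meanlog <- log(config$fn_scale) - sdlog^2 / 2
      fn <- pmax(1, round(rlnorm(m, meanlog, sdlog)))
      return(list(edges = edges, fa = fa, fn = fn, module = module,
                  n_nodes = n))
    }
  }
  abort("Could not draw a connected backbone in 100 attempts.")
}

#' Sample one subject's structural matrices from the template
#'
#' Subject fractional anisotropy jitters the template values (sd 0.03,
#' clipped to `fa_range`); fiber counts get multiplicative lognormal jitter
#' and are rounded to positive integers, so FA and FN always share the same
#' zero pattern. Patients (`group = "HS"`) additionally have fiber counts of
#' edges incident to `affected_nodes` multiplied by `attenuation`, and every
#' edge deleted independently with probability `edge_drop_prob`; draws that
#' isolate a node are rejected and resampled.
#'
#' @param template Output of [make_group_template()].
#' @param group `"HS"` or `"HC"`.
#' @param config A [cohort_config()].
#' @return List with `fa` and `fn` node x node matrices.
#' @export
sample_subject_sc <- function(template, group, config) {
  group <- match.arg(group, c("HS", "HC"))
  n <- template$n_nodes
  m <- nrow(template$edges)
  for (attempt in seq_len(100)) {
    fa_e <- template$fa + rnorm(m, 0, 0.03)
    fa_e <- pmin(pmax(fa_e, config$fa_range[1]), config$fa_range[2])
    fn_e <- pmax(1, round(template$fn * exp(rnorm(m, 0, 0.2))))
    keep <- rep(TRUE, m)
    if (group == "HS") {
      hub <- template$edges[, 1] %in% config$affected_nodes |
        template$edges[, 2] %in% config$affected_nodes
      fn_e[hub] <- pmax(1, round(fn_e[hub] * config$attenuation))
      if (config$edge_drop_prob > 0) {
        keep <- runif(m) >= config$edge_drop_prob
      }
    }
    edges <- template$edges[keep, , drop = FALSE]
    deg <- tabulate(edges, nbins = n)
    if (any(deg == 0)) next
    labs <- default_labels(n)
    fa <- matrix(0, n, n, dimnames = list(labs, labs))
    fn <- matrix(0, n, n, dimnames = list(labs, labs))
    fa[edges] <- fa_e[keep]; fa[edges[, c(2, 1)]] <- fa_e[keep]
    fn[edges] <- fn_e[keep]; fn[edges[, c(2, 1)]] <- fn_e[keep]
    return(list(fa = fa, fn = fn))
  }
  abort("Could not sample a subject without isolated nodes in 100 attempts.")
}

#' Simulate node time series structurally coupled to a connectivity matrix
#'
#' Draws `t_points` observations from a zero-mean multivariate normal whose
#' covariance is the unit-diagonal normalization of `SC + c I`,
#' `Sigma = D^{-1/2} (SC + c I) D^{-1/2}` with `D = diag(SC + c I)` and
#' `c = 1.05 |lambda_min(SC)| + 0.1`, which is positive definite by
#' construction, then adds independent Gaussian observation noise. Empirical
#' correlations are therefore positively associated with structural weights.
#'
#' @param sc_weight Symmetric non-negative structural weight matrix.
#' @param t_points Number of time points.
#' @param config A [cohort_config()] (supplies `fc_noise_sd`).
#' @return Timepoints x nodes matrix with node labels as column names.
#' @export
simulate_timeseries <- function(sc_weight, t_points, config) {
  sc <- as.matrix(sc_weight)
  n <- nrow(sc)
  if (any(sc < 0) || max(abs(sc - t(sc))) > 1e-8) {
    abort("`sc_weight` must be symmetric and non-negative.")
  }
  lam_min <- min(eigen(sc, symmetric = TRUE, only.values = TRUE)$values)
  cshift <- 1.05 * abs(lam_min) + 0.1
  a <- sc + diag(cshift, n)
  dd <- 1 / sqrt(diag(a))
  sigma <- a * tcrossprod(dd)
  ch <- tryCatch(chol(sigma), error = function(e) {
    abort(paste0("Target covariance is not positive definite: ",
                 conditionMessage(e)))
  })
  z <- matrix(rnorm(t_points * n), t_points, n)
  ts <- z %*% ch +
    matrix(rnorm(t_points * n, 0, config$fc_noise_sd), t_points, n)
  colnames(ts) <- colnames(sc) %||% default_labels(n)
  ts
}

#' Attach clinical scale scores to subject metrics
#'
#' Generates WISC, WMS and ADHD scores for patient rows from the noiseless
#' generator-side network metrics: WISC decreases with path-length AUC, WMS
#' increases with the precuneus-proxy nodal-efficiency AUC, ADHD increases
#' with path-length AUC. Slopes act on within-group z-scores, so scale means
#' sit at the configured centers regardless of the metric scale. Controls
#' get `NA` scores (scales are administered to the patient group only).
#'
#' @param subject_metrics Tibble with `subject_id`, `group`, `lp_auc`,
#'   `eg_auc`, `ne_probe_auc`.
#' @param config A [cohort_config()].
#' @return `subject_metrics` with `wisc`, `wms`, `adhd` columns appended.
#' @export
assign_clinical <- function(subject_metrics, config) {
  sm <- as_tibble(subject_metrics)
  hs <- sm$group == "HS"
  zscore <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  n_hs <- sum(hs)
  sm$wisc <- sm$wms <- sm$adhd <- NA_real_
  if (n_hs > 0) {
    link <- config$scale_link
    z_lp <- zscore(sm$lp_auc[hs])
    z_ne <- zscore(sm$ne_probe_auc[hs])
    sm$wisc[hs] <- link$wisc["center"] - link$wisc["slope"] * z_lp +
      rnorm(n_hs, 0, link$wisc["noise"])
    sm$wms[hs] <- link$wms["center"] + link$wms["slope"] * z_ne +
      rnorm(n_hs, 0, link$wms["noise"])
    sm$adhd[hs] <- link$adhd["center"] + link$adhd["slope"] * z_lp +
      rnorm(n_hs, 0, link$adhd["noise"])
  }
  sm
}

#' Generate a full synthetic two-group cohort
#'
#' Draws the shared backbone, per-subject structural matrices, optional
#' structurally coupled node time series, demographics (ages truncated-normal
#' N(9.0, 2.2) on [6, 13]; one Bernoulli(0.6) male/female vector shared by
#' both groups so sexes are matched; patient disease duration
#' truncated-normal N(4.89, 3.11) at >= 0.5 months) and clinical scores.
#' With `dir` given, everything is written in the package's text formats:
#' `manifest.tsv` plus `<subject>_fa.tsv`, `<subject>_fn.tsv` and
#' `<subject>_ts.tsv` per subject.
#'
#' @param config A [cohort_config()].
#' @param dir Optional output directory.
#' @param timeseries Generate functional time series? Skipping them speeds up
#'   structure-only simulation studies.
#' @param clinical Attach clinical scores (requires a small structural metric
#'   sweep per subject)?
#' @param grid Sparsity grid used for the generator-side metric sweep behind
#'   the clinical links.
#' @return List with `manifest` (tibble), `subjects` (named list of
#'   `fa`/`fn`/`sc`/`ts`), `template`, and `metrics` (generator-side AUC
#'   tibble when `clinical = TRUE`).
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL,
                            timeseries = TRUE, clinical = TRUE,
                            grid = sparsity_grid()) {
  set.seed(config$seed)
  template <- make_group_template(config)
  n_g <- config$n_per_group
  ids <- c(sprintf("HS%03d", seq_len(n_g)), sprintf("HC%03d", seq_len(n_g)))
  groups <- rep(c("HS", "HC"), each = n_g)

  rtruncnorm <- function(n, mean, sd, lo, hi) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        v <- rnorm(1, mean, sd)
        if (v >= lo && v <= hi) break
      }
      out[i] <- v
    }
    out
  }
  sex_vec <- ifelse(rbinom(n_g, 1, 0.6) == 1, "M", "F")
  manifest <- tibble(
    subject_id = ids,
    group = factor(groups, levels = c("HC", "HS")),
    age = rtruncnorm(2 * n_g, 9.0, 2.2, 6, 13),
    sex = factor(rep(sex_vec, 2), levels = c("F", "M")),
    duration = c(rtruncnorm(n_g, 4.89, 3.11, 0.5, Inf), rep(NA_real_, n_g))
  )

  subjects <- vector("list", 2 * n_g)
  names(subjects) <- ids
  metrics <- vector("list", 2 * n_g)
  for (si in seq_along(ids)) {
    sc_pair <- sample_subject_sc(template, groups[si], config)
    sc <- build_sc(sc_pair$fa, sc_pair$fn)
    ts <- if (timeseries) {
      simulate_timeseries(sc, config$t_points, config)
    }
    subjects[[si]] <- list(fa = sc_pair$fa, fn = sc_pair$fn, sc = sc, ts = ts)
    if (clinical) {
      au <- distance_aucs(sc, grid, probe_node = config$pcun_node)
      metrics[[si]] <- tibble(subject_id = ids[si], group = groups[si],
                              lp_auc = au[["lp_auc"]], eg_auc = au[["eg_auc"]],
                              ne_probe_auc = au[["ne_probe_auc"]])
    }
  }

  metrics_tbl <- NULL
  if (clinical) {
    metrics_tbl <- assign_clinical(bind_rows(metrics), config)
    manifest <- manifest %>%
      left_join(metrics_tbl %>% select("subject_id", "wisc", "wms", "adhd"),
                by = "subject_id")
  } else {
    manifest$wisc <- manifest$wms <- manifest$adhd <- NA_real_
  }

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_manifest(manifest, file.path(dir, "manifest.tsv"))
    for (id in ids) {
      write_matrix(subjects[[id]]$fa, file.path(dir, paste0(id, "_fa.tsv")))
      write_matrix(subjects[[id]]$fn, file.path(dir, paste0(id, "_fn.tsv")))
      if (timeseries) {
        write_timeseries(subjects[[id]]$ts,
                         file.path(dir, paste0(id, "_ts.tsv")))
      }
    }
  }

  list(manifest = manifest, subjects = subjects, template = template,
       metrics = metrics_tbl)
}
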