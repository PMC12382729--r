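GLOBAL_METRICS <- c("Cp", "Lp", "Eg", "Eloc")
SW_METRICS <- c("gamma", "lambda", "sigma")
NODAL_METRICS <- c("Dc", "Bc", "Ne", "Nle", "NCp")

#' Metric curves across the sparsity grid
#'
#' Thresholds a connectivity matrix at every sparsity in the grid and
#' computes the requested metrics, returning one long tibble of metric values
#' per threshold (and per node for nodal metrics). When the requested edge
#' count exceeds the number of available non-zero edges the thresholded
#' network saturates; saturated thresholds share one computation, so sweeps
#' over sparse structural matrices stay cheap.
#'
#' @param mat Symmetric connectivity matrix.
#' @param grid Sparsity grid from [sparsity_grid()].
#' @param metrics Character vector drawn from `Cp, Lp, Eg, Eloc` (global),
#'   `gamma, lambda, sigma` (small-world; requires `n_null > 0`), and
#'   `Dc, Bc, Ne, Nle, NCp` (nodal).
#' @param policy Negative-weight policy for thresholding (see
#'   [threshold_proportional()]).
#' @param n_null Null networks per threshold for small-world normalization.
#' @param seed Optional seed; each threshold uses a derived substream so
#'   curves are reproducible.
#' @return Tibble of class `ns_curves`: `sparsity`, `metric`, `node`
#'   (`NA` for global metrics), `value`.
#' @export
metric_curves <- function(mat, grid = sparsity_grid(),
                          metrics = c("Cp", "Lp", "Eg", "Eloc"),
                          policy = "zero", n_null = 0, seed = NULL) {
  bad <- setdiff(metrics, c(GLOBAL_METRICS, SW_METRICS, NODAL_METRICS))
  if (length(bad) > 0) {
    abort(paste0("Unknown metric(s): ", paste(bad, collapse = ", ")))
  }
  want_sw <- any(metrics %in% SW_METRICS)
  if (want_sw && n_null < 1) {
    abort("Small-world metrics need `n_null` >= 1.")
  }
  want_nodal <- any(metrics %in% NODAL_METRICS)
  global_set <- intersect(GLOBAL_METRICS, metrics)
  compute_set <- union(global_set, if (want_sw) c("Cp", "Lp"))

  cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    s <- grid[gi]
    tn <- threshold_proportional(mat, s, policy = policy)
    key <- as.character(tn$retained_edges)
    if (!is.null(cache[[key]])) {
      res <- cache[[key]]
    } else {
      res <- list()
      if (length(compute_set) > 0) {
        res$global <- compute_global(tn, metrics = compute_set)
      }
      if (want_sw) {
        ens_seed <- if (is.null(seed)) NULL else substream_seed(seed, gi)
        ens <- build_null_ensemble(tn, n_null = n_null, seed = ens_seed)
        res$sw <- normalize_small_world(res$global, ens)
      }
      if (want_nodal) res$nodal <- compute_nodal(tn)
      cache[[key]] <- res
    }
    parts <- list()
    if (length(global_set) > 0) {
      parts$global <- tibble(
        sparsity = s, metric = global_set, node = NA_integer_,
        value = as.numeric(res$global[1, global_set])
      )
    }
    if (want_sw) {
      sw_set <- intersect(SW_METRICS, metrics)
      parts$sw <- tibble(
        sparsity = s, metric = sw_set, node = NA_integer_,
        value = as.numeric(res$sw[1, sw_set])
      )
    }
    if (want_nodal) {
      nodal_set <- intersect(NODAL_METRICS, metrics)
      parts$nodal <- res$nodal %>%
        tidyr::pivot_longer(dplyr::all_of(nodal_set), names_to = "metric",
                            values_to = "value") %>%
        mutate(sparsity = s) %>%
        select("sparsity", "metric", "node", "value")
    }
    rows[[gi]] <- bind_rows(parts)
  }
  out <- bind_rows(rows)
  class(out) <- c("ns_curves", class(out))
  attr(out, "grid") <- grid
  out
}

#' AUC summary of metric curves
#'
#' Integrates every metric (and node, for nodal metrics) over the sparsity
#' grid, giving one threshold-free value per metric.
#'
#' @param curves An `ns_curves` tibble from [metric_curves()].
#' @param rule Integration rule, `"trapezoid"` or `"rectangle"`.
#' @return Tibble: `metric`, `node`, `auc`.
#' @export
auc_table <- function(curves, rule = c("trapezoid", "rectangle")) {
  rule <- match.arg(rule)
  curves %>%
    as_tibble() %>%
    group_by(.data$metric, .data$node) %>%
    arrange(.data$sparsity, .by_group = TRUE) %>%
    summarise(auc = integrate_auc(.data$value, .data$sparsity, rule = rule),
              .groups = "drop")
}

# Fast distance-only sweep used by the cohort generator and recovery tests:
# AUC of Lp and Eg plus the nodal-efficiency AUC of one probe node, with
# saturation caching.
distance_aucs <- function(mat, grid, probe_node) {
  n <- nrow(mat)
  cache <- list()
  lp <- eg <- ne <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    tn <- threshold_proportional(mat, grid[gi])
    key <- as.character(tn$retained_edges)
    if (is.null(cache[[key]])) {
      d <- shortest_path_lengths(tn$weights)
      off <- d[row(d) != col(d)]
      finite <- is.finite(off)
      inv <- 1 / d[probe_node, -probe_node]
      inv[!is.finite(inv)] <- 0
      cache[[key]] <- c(
        Lp = if (any(finite)) mean(off[finite]) else 0,
        Eg = efficiency_from_dist(d),
        Ne = mean(inv)
      )
    }
    v <- cache[[key]]
    lp[gi] <- v["Lp"]; eg[gi] <- v["Eg"]; ne[gi] <- v["Ne"]
  }
  c(lp_auc = integrate_auc(lp, grid),
    eg_auc = integrate_auc(eg, grid),
    ne_probe_auc = integrate_auc(ne, grid))
}

#' Mean small-worldness of a set of structural networks over the grid
#'
#' For each subject matrix, thresholds across the grid and computes sigma
#' with a degree-preserving null ensemble per network (saturated thresholds
#' share their ensemble). Returns per-subject, per-threshold sigma values.
#'
#' @param mats Named list of symmetric connectivity matrices.
#' @param grid Sparsity grid.
#' @param n_null Null networks per evaluation.
#' @param seed Integer seed (substreams derived per subject).
#' @return Tibble: `subject_id`, `sparsity`, `gamma`, `lambda`, `sigma`.
#' @export
cohort_small_world <- function(mats, grid = sparsity_grid(), n_null = 100,
                               seed = 1L) {
  ids <- names(mats) %||% as.character(seq_along(mats))
  res <- vector("list", length(mats))
  for (si in seq_along(mats)) {
    cur <- metric_curves(mats[[si]], grid = grid,
                         metrics = c("gamma", "lambda", "sigma"),
                         n_null = n_null,
                         seed = substream_seed(seed, si))
    res[[si]] <- cur %>%
      tidyr::pivot_wider(names_from = "metric", values_from = "value") %>%
      mutate(subject_id = ids[si]) %>%
      select("subject_id", "sparsity", "gamma", "lambda", "sigma")
  }
  bind_rows(res)
}
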