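#' Plot metric curves across the sparsity grid
#'
#' Global metrics are drawn as one line per metric (faceted); nodal metrics
#' are summarized as per-threshold node means.
#'
#' @param object An `ns_curves` tibble from [metric_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ns_curves <- function(object, ...) {
  df <- as_tibble(object) %>%
    group_by(.data$sparsity, .data$metric) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  ggplot(df, aes(x = .data$sparsity, y = .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "sparsity (fraction of edges retained)", y = "metric value") +
    theme_minimal()
}

#' Plot group contrasts as estimates with significance flags
#'
#' @param object An `ns_contrasts` tibble from [group_contrasts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ns_contrasts <- function(object, ...) {
  df <- as_tibble(unclass_tbl(object)) %>%
    mutate(label = ifelse(is.na(.data$node), .data$metric,
                          paste0(.data$metric, "[", .data$node, "]")))
  ggplot(df, aes(x = .data$label, y = .data$estimate,
                 colour = .data$significant)) +
    geom_point() +
    geom_hline(yintercept = 0, linetype = 2) +
    facet_wrap(~network, scales = "free_x") +
    labs(x = NULL, y = "group effect (HS - HC, adjusted)",
         colour = "significant") +
    theme_minimal()
}

#' Plot per-subject SC-FC coupling by group
#'
#' @param coupling Coupling tibble from [cohort_coupling()].
#' @return A ggplot object.
#' @export
plot_coupling <- function(coupling) {
  ggplot(coupling, aes(x = .data$group, y = .data$r)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.6) +
    labs(x = NULL, y = "SC-FC coupling (Pearson r)") +
    theme_minimal()
}
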