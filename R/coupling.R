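#' Rank-based inverse-normal (van der Waerden) transform
#'
#' Rescales values to a Gaussian shape: each value maps to
#' `qnorm(rank / (n + 1))` with average ranks for ties. The result is
#' invariant under any strictly monotone transform of the input.
#'
#' @param values Numeric vector, length >= 3, not all identical.
#' @return Gaussianized numeric vector.
#' @export
#' @examples
#' gaussianize(c(5, 1, 9))  # 0, -0.6745, 0.6745
gaussianize <- function(values) {
  if (length(values) < 3) abort("Gaussianization needs at least 3 values.")
  if (any(!is.finite(values))) abort("Non-finite values cannot be ranked.")
  if (max(values) == min(values)) {
    abort("All values identical: rank transform is degenerate.")
  }
  r <- rank(values, ties.method = "average")
  qnorm(r / (length(values) + 1))
}

#' Per-subject structure-function coupling
#'
#' Selects the non-zero structural connections of the (unthresholded)
#' structural matrix, rescales their weights to a Gaussian distribution by
#' rank-based inverse-normal transform, and correlates them (Pearson) with
#' the functional connectivity values at the same edges. One coupling value
#' per subject.
#'
#' @param sc Structural connectivity matrix (non-negative, symmetric).
#' @param fc Functional connectivity matrix with matching labels/shape.
#' @return One-row tibble: `n_edges`, `r`.
#' @export
sc_fc_coupling <- function(sc, fc) {
  sc <- as.matrix(sc); fc <- as.matrix(fc)
  if (!all(dim(sc) == dim(fc))) {
    abort("SC and FC matrices must share the same shape.")
  }
  if (!is.null(dimnames(sc)) && !is.null(dimnames(fc)) &&
      !identical(dimnames(sc), dimnames(fc))) {
    abort("SC and FC matrices must share the same node labels.")
  }
  ut <- upper.tri(sc)
  sel <- ut & sc > 0
  n_edges <- sum(sel)
  if (n_edges < 3) {
    abort(paste0("Only ", n_edges,
                 " non-zero structural edges; need at least 3."))
  }
  sc_g <- gaussianize(sc[sel])
  tibble(n_edges = n_edges, r = stats::cor(sc_g, fc[sel]))
}

#' Coupling table for a whole cohort
#'
#' @param subjects Named list of subject bundles with `sc` and `fc` (or `ts`,
#'   from which FC is built) entries.
#' @param manifest Cohort manifest tibble (for group labels).
#' @return Tibble: `subject_id`, `group`, `n_edges`, `r`.
#' @export
cohort_coupling <- function(subjects, manifest) {
  rows <- imap(subjects, function(sub, id) {
    fc <- sub$fc %||% build_fc(sub$ts)
    sc_fc_coupling(sub$sc, fc) %>% mutate(subject_id = id, .before = 1)
  })
  bind_rows(rows) %>%
    left_join(manifest %>% select("subject_id", "group"), by = "subject_id") %>%
    select("subject_id", "group", "n_edges", "r")
}
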