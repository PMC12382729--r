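# Session-memoized fixtures so expensive cohorts are generated once per run.
.fixtures <- new.env(parent = emptyenv())

# Default-condition cohort (36 + 36 subjects, structural only).
default_sc_cohort <- function() {
  if (is.null(.fixtures$sc_cohort)) {
    .fixtures$sc_cohort <- generate_cohort(
      cohort_config(seed = 101L), timeseries = FALSE, clinical = TRUE
    )
  }
  .fixtures$sc_cohort
}

# Small cohort with time series for coupling / pipeline-level tests.
small_full_cohort <- function() {
  if (is.null(.fixtures$small_cohort)) {
    .fixtures$small_cohort <- generate_cohort(
      cohort_config(n_per_group = 4, t_points = 120, seed = 202L),
      timeseries = TRUE, clinical = TRUE
    )
  }
  .fixtures$small_cohort
}

null_cohort_config <- function(seed) {
  cohort_config(
    attenuation = 1, edge_drop_prob = 0,
    scale_link = list(wisc = c(center = 73.64, slope = 0, noise = 8),
                      wms = c(center = 75.08, slope = 0, noise = 7),
                      adhd = c(center = 24.61, slope = 0, noise = 6)),
    seed = seed
  )
}

make_manifest <- function(n_per_group = 36) {
  n <- 2 * n_per_group
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = factor(rep(c("HS", "HC"), each = n_per_group),
                   levels = c("HC", "HS")),
    age = runif(n, 6, 13),
    sex = factor(rep(c("M", "F"), length.out = n), levels = c("F", "M")),
    duration = c(runif(n_per_group, 1, 10), rep(NA_real_, n_per_group)),
    wisc = c(rnorm(n_per_group, 73, 12), rep(NA_real_, n_per_group)),
    wms = c(rnorm(n_per_group, 75, 11), rep(NA_real_, n_per_group)),
    adhd = c(rnorm(n_per_group, 25, 8), rep(NA_real_, n_per_group))
  )
}
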