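#' Run the full dual-modality network analysis pipeline
#'
#' Executes, in order: cohort acquisition (synthetic generation or reading
#' from `input_dir`), time-series preprocessing (detrend, band-pass),
#' connectivity construction (FC correlation, SC = FA x FN), the
#' proportional-threshold metric sweep with small-world normalization and AUC
#' summarization, SC-FC coupling, and the group-level statistical battery.
#' All result tables are written as TSV, with a JSON run summary and a log
#' recording the seed of every stochastic stage. Any stage failure aborts
#' with the stage name.
#'
#' @param config A `netsweep_config`, or path to a YAML config file (see
#'   [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @param input_dir Directory with `manifest.tsv` and per-subject
#'   `<id>_fa.tsv` / `<id>_fn.tsv` / `<id>_ts.tsv`; ignored when simulating.
#' @param cohort Optional [cohort_config()] overriding `config$cohort` for
#'   simulation.
#' @return Invisibly, a list with the result tables and output paths.
#' @export
run_pipeline <- function(config, out_dir, input_dir = NULL, cohort = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "netsweep_config")) {
    abort("`config` must be a netsweep_config or a path to one.")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character()
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  stage <- function(name, expr) {
    log_msg("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      log_msg("stage ", name, " FAILED: ", conditionMessage(e))
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  simulate <- isTRUE(config$simulate) || is.null(input_dir)
  log_msg("seed = ", config$seed, "; simulate = ", simulate)

  grid <- sparsity_grid(config$sparsity_start, config$sparsity_stop,
                        config$sparsity_step)

  acquired <- stage("acquire", {
    if (simulate) {
      ccfg <- cohort %||% config$cohort %||% cohort_config(
        n_nodes = config$n_nodes, seed = substream_seed(config$seed, 1)
      )
      log_msg("simulating cohort with generator seed ", ccfg$seed)
      generate_cohort(ccfg, grid = grid)
    } else {
      manifest <- read_manifest(file.path(input_dir, "manifest.tsv"))
      subjects <- lapply(manifest$subject_id, function(id) {
        fa <- read_matrix(file.path(input_dir, paste0(id, "_fa.tsv")),
                          config$n_nodes)
        fn <- read_matrix(file.path(input_dir, paste0(id, "_fn.tsv")),
                          config$n_nodes)
        ts_path <- file.path(input_dir, paste0(id, "_ts.tsv"))
        ts <- if (file.exists(ts_path)) read_timeseries(ts_path)
        list(fa = fa, fn = fn, sc = build_sc(fa, fn), ts = ts)
      })
      names(subjects) <- manifest$subject_id
      list(manifest = manifest, subjects = subjects)
    }
  })
  manifest <- acquired$manifest
  subjects <- acquired$subjects

  subjects <- stage("preprocess", {
    lapply(subjects, function(sub) {
      if (!is.null(sub$ts)) {
        sub$ts <- preprocess_timeseries(sub$ts, low = config$band[1],
                                        high = config$band[2],
                                        tr = config$tr)
      }
      sub
    })
  })

  subjects <- stage("build", {
    lapply(subjects, function(sub) {
      if (!is.null(sub$ts)) sub$fc <- build_fc(sub$ts)
      sub
    })
  })

  sweep_res <- stage("metrics", {
    all_metrics <- c(GLOBAL_METRICS, SW_METRICS, NODAL_METRICS)
    rows <- imap(subjects, function(sub, id) {
      nets <- list(SCN = sub$sc)
      if (!is.null(sub$fc)) nets$FCN <- sub$fc
      imap(nets, function(mat, nw) {
        metric_curves(
          mat, grid = grid, metrics = all_metrics,
          policy = config$negative_fc_policy,
          n_null = config$n_null,
          seed = substream_seed(config$seed,
                                2L + match(id, names(subjects)) * 2L +
                                  (nw == "FCN"))
        ) %>% mutate(subject_id = id, network = nw)
      }) %>% bind_rows()
    })
    bind_rows(rows) %>%
      select("subject_id", "network", "metric", "sparsity", "node", "value")
  })
  # small-world indices can be undefined on degenerate thresholded networks
  # (zero null means); those curves are excluded from AUC summarization
  complete_curves <- sweep_res %>%
    group_by(.data$subject_id, .data$network, .data$metric, .data$node) %>%
    filter(all(is.finite(.data$value))) %>%
    ungroup()
  n_dropped <- nrow(sweep_res) - nrow(complete_curves)
  if (n_dropped > 0) {
    log_msg("dropped ", n_dropped,
            " curve rows with undefined values before AUC")
  }
  auc <- complete_curves %>%
    group_by(.data$subject_id, .data$network, .data$metric, .data$node) %>%
    arrange(.data$sparsity, .by_group = TRUE) %>%
    summarise(auc = integrate_auc(.data$value, .data$sparsity,
                                  rule = config$auc_rule),
              .groups = "drop")

  coupling_tbl <- stage("couple", {
    has_fc <- !vapply(subjects, function(s) is.null(s$fc), logical(1))
    if (!any(has_fc)) {
      NULL
    } else {
      cohort_coupling(subjects[has_fc], manifest)
    }
  })

  stats_res <- stage("stats", {
    demo <- demographic_table(manifest)
    global_auc <- auc %>% filter(is.na(.data$node))
    nodal_auc <- auc %>% filter(!is.na(.data$node))
    global_contr <- group_contrasts(global_auc, manifest,
                                    alpha = config$nodal_alpha)
    nodal_contr <- if (nrow(nodal_auc) > 0) {
      group_contrasts(nodal_auc, manifest, alpha = config$nodal_alpha)
    }
    coup_test <- if (!is.null(coupling_tbl)) {
      permutation_test(coupling_tbl$r, coupling_tbl$group,
                       n_perm = config$n_perm,
                       seed = substream_seed(config$seed, 999))
    }
    clin <- if (any(!is.na(manifest$wisc))) {
      clinical_correlations(global_auc, manifest)
    }
    list(demographics = demo, global = global_contr, nodal = nodal_contr,
         coupling = coup_test, clinical = clin)
  })

  paths <- stage("write", {
    p <- list(
      curves = file.path(out_dir, "metric_curves.tsv"),
      auc = file.path(out_dir, "auc.tsv"),
      coupling = file.path(out_dir, "coupling.tsv"),
      demographics = file.path(out_dir, "stats_demographics.tsv"),
      stats_global = file.path(out_dir, "stats_global.tsv"),
      stats_nodal = file.path(out_dir, "stats_nodal.tsv"),
      stats_coupling = file.path(out_dir, "stats_coupling.tsv"),
      clinical = file.path(out_dir, "stats_clinical_correlations.tsv"),
      summary = file.path(out_dir, "run_summary.json")
    )
    readr::write_tsv(sweep_res, p$curves, progress = FALSE)
    readr::write_tsv(auc, p$auc, progress = FALSE)
    if (!is.null(coupling_tbl)) {
      readr::write_tsv(coupling_tbl, p$coupling, progress = FALSE)
    }
    readr::write_tsv(stats_res$demographics, p$demographics,
                     progress = FALSE)
    readr::write_tsv(tidy(stats_res$global), p$stats_global,
                     progress = FALSE)
    if (!is.null(stats_res$nodal)) {
      readr::write_tsv(tidy(stats_res$nodal), p$stats_nodal,
                       progress = FALSE)
    }
    if (!is.null(stats_res$coupling)) {
      readr::write_tsv(tidy(stats_res$coupling), p$stats_coupling,
                       progress = FALSE)
    }
    if (!is.null(stats_res$clinical)) {
      readr::write_tsv(stats_res$clinical, p$clinical, progress = FALSE)
    }
    summary_obj <- list(
      seed = config$seed,
      simulate = simulate,
      n_subjects = nrow(manifest),
      n_nodes = config$n_nodes,
      sparsity = list(start = config$sparsity_start,
                      stop = config$sparsity_stop,
                      step = config$sparsity_step),
      n_null = config$n_null,
      n_perm = config$n_perm,
      outputs = basename(unname(unlist(p[names(p) != "summary"])))
    )
    jsonlite::write_json(summary_obj, p$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    p
  })
  log_msg("pipeline finished")

  invisible(list(manifest = manifest, curves = sweep_res, auc = auc,
                 coupling = coupling_tbl, stats = stats_res, paths = paths))
}
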