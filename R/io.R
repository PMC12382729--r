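#' Read a cohort manifest
#'
#' The manifest is a delimited text table (TSV or CSV, header row) with one
#' row per subject: `subject_id`, `group` (HS = patients, HC = controls,
#' case-insensitive), `age` (years), `sex` (M/F), `duration` (months, may be
#' empty for controls) and optional clinical scale columns `wisc`, `wms`,
#' `adhd`. Missing scale cells become `NA`.
#'
#' @param path Path to the manifest file.
#' @return A tibble with typed columns; `group` and `sex` are factors.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("Manifest not found: ", path))
  delim <- detect_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  required <- c("subject_id", "group", "age", "sex")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Manifest lacks required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    warn("Manifest is empty after the header row.")
    return(tibble(
      subject_id = character(), group = factor(levels = c("HC", "HS")),
      age = numeric(), sex = factor(levels = c("F", "M")),
      duration = numeric(), wisc = numeric(), wms = numeric(),
      adhd = numeric()
    ))
  }

  dup <- which(duplicated(df$subject_id))
  if (length(dup) > 0) {
    abort(paste0("Duplicate subject_id at manifest row ", dup[1], ": ",
                 df$subject_id[dup[1]]))
  }
  grp <- toupper(trimws(df$group))
  bad_grp <- which(!grp %in% c("HS", "HC"))
  if (length(bad_grp) > 0) {
    abort(paste0("Unknown group label at manifest row ", bad_grp[1], ": '",
                 df$group[bad_grp[1]], "' (expected HS or HC)"))
  }
  age <- suppressWarnings(as.numeric(df$age))
  bad_age <- which(is.na(age) | age <= 0)
  if (length(bad_age) > 0) {
    abort(paste0("Non-numeric or non-positive age at manifest row ",
                 bad_age[1], ": '", df$age[bad_age[1]], "'"))
  }
  sex <- toupper(trimws(df$sex))
  bad_sex <- which(!sex %in% c("M", "F"))
  if (length(bad_sex) > 0) {
    abort(paste0("Unknown sex code at manifest row ", bad_sex[1], ": '",
                 df$sex[bad_sex[1]], "'"))
  }
  num_or_na <- function(col) {
    if (!col %in% names(df)) return(rep(NA_real_, nrow(df)))
    suppressWarnings(as.numeric(df[[col]]))
  }
  duration <- num_or_na("duration")
  if (any(!is.na(duration) & duration < 0)) {
    abort("Negative disease duration in manifest.")
  }

  tibble(
    subject_id = df$subject_id,
    group = factor(grp, levels = c("HC", "HS")),
    age = age,
    sex = factor(sex, levels = c("F", "M")),
    duration = duration,
    wisc = num_or_na("wisc"),
    wms = num_or_na("wms"),
    adhd = num_or_na("adhd")
  )
}

#' Write a cohort manifest
#'
#' @param manifest A manifest tibble as returned by [read_manifest()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Read a connectivity matrix from a delimited text file
#'
#' Accepts whitespace- or comma-delimited square numeric tables with no
#' header. The matrix is symmetrized by averaging (with a warning when the
#' asymmetry exceeds 1e-8) and the diagonal is forced to zero.
#'
#' @param path Path to the matrix file.
#' @param n_nodes Expected dimension; checked when given.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
read_matrix <- function(path, n_nodes = NULL) {
  if (!file.exists(path)) abort(paste0("Matrix file not found: ", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          colClasses = "numeric")
  m <- as.matrix(df)
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) {
    abort(paste0("Matrix in ", path, " is not square: ", nrow(m), "x",
                 ncol(m)))
  }
  if (!is.null(n_nodes) && nrow(m) != n_nodes) {
    abort(paste0("Matrix in ", path, " has dimension ", nrow(m),
                 ", expected ", n_nodes))
  }
  if (any(!is.finite(m))) {
    abort(paste0("Matrix in ", path, " contains NaN/Inf cells."))
  }
  if (max(abs(m - t(m))) > 1e-8) {
    warn(paste0("Matrix in ", path,
                " is asymmetric; symmetrizing by averaging."))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Write a connectivity matrix as delimited text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces them to within 1e-12.
#'
#' @param mat Numeric matrix.
#' @param path Output path.
#' @param sep Field delimiter (tab by default).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, sep = "\t") {
  txt <- apply(mat, 1, function(r) paste(sprintf("%.17g", r), collapse = sep))
  writeLines(txt, path)
  invisible(path)
}

#' Read a node time-series table
#'
#' Expects a header row of region labels; each subsequent row is one time
#' point. Label order defines node order downstream.
#'
#' @param path Path to the time-series file.
#' @param labels Optional character vector of expected region labels; a
#'   mismatch is an error.
#' @return A timepoints x nodes numeric matrix with labels as column names.
#' @export
read_timeseries <- function(path, labels = NULL) {
  if (!file.exists(path)) abort(paste0("Time-series file not found: ", path))
  delim <- detect_delim(path)
  lab <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  if (anyDuplicated(lab)) {
    abort(paste0("Duplicated region label in ", path, ": ",
                 lab[duplicated(lab)][1]))
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  names(df) <- lab
  if (!is.null(labels) && !identical(lab, as.character(labels))) {
    abort(paste0("Region labels in ", path,
                 " do not match the expected parcellation."))
  }
  m <- as.matrix(df)
  if (any(!is.finite(m))) abort(paste0("Time series in ", path,
                                       " contains non-finite values."))
  storage.mode(m) <- "double"
  colnames(m) <- lab
  zero_var <- which(apply(m, 2, stats::sd) == 0)
  if (length(zero_var) > 0) {
    warn(paste0("Constant time series for node(s): ",
                paste(lab[zero_var], collapse = ", "),
                " (degenerate variance handled downstream)."))
  }
  m
}

#' Write a node time-series table
#'
#' @param ts Timepoints x nodes matrix with column names as region labels.
#' @param path Output path (tab-delimited, header row of labels).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  if (is.null(colnames(ts))) {
    colnames(ts) <- default_labels(ncol(ts))
  }
  header <- paste(colnames(ts), collapse = "\t")
  body <- apply(ts, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

default_labels <- function(n) sprintf("N%03d", seq_len(n))

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else if (grepl(",", first, fixed = TRUE)) "," else " "
}
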