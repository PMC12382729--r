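#' Remove per-node linear trends
#'
#' Fits an ordinary least-squares line over time to every node signal and
#' returns the residuals, so slow scanner drift does not leak into the
#' correlation structure. Column means become zero.
#'
#' @param ts Timepoints x nodes numeric matrix.
#' @return Detrended matrix of the same shape.
#' @export
detrend_linear <- function(ts) {
  ts <- as.matrix(ts)
  n_t <- nrow(ts)
  if (n_t < 3) abort("Detrending needs at least 3 time points.")
  x <- cbind(1, seq_len(n_t))
  res <- stats::lm.fit(x, ts)$residuals
  res <- as.matrix(res)
  dimnames(res) <- dimnames(ts)
  res
}

#' Regress nuisance signals out of node time series
#'
#' Projects every node signal onto the orthogonal complement of
#' `[intercept, confounds]` (head-motion parameters, tissue signals, ...).
#' Constant or all-zero confound columns are dropped with a message; a
#' rank-deficient design after that is an error naming the collinear columns.
#'
#' @param ts Timepoints x nodes matrix.
#' @param confounds Timepoints x k matrix or data frame of nuisance
#'   regressors.
#' @return Residual matrix, same shape as `ts`.
#' @export
regress_confounds <- function(ts, confounds) {
  ts <- as.matrix(ts)
  cf <- as.matrix(confounds)
  if (nrow(cf) != nrow(ts)) {
    abort("Confound table must have the same number of time points.")
  }
  if (is.null(colnames(cf))) colnames(cf) <- paste0("c", seq_len(ncol(cf)))
  keep <- apply(cf, 2, function(v) stats::sd(v) > 0)
  if (any(!keep)) {
    inform(paste0("Dropping constant confound column(s): ",
                  paste(colnames(cf)[!keep], collapse = ", ")))
  }
  cf <- cf[, keep, drop = FALSE]
  x <- cbind(intercept = 1, cf)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[seq.int(qx$rank + 1, ncol(x))]]
    abort(paste0("Confound design is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  res <- stats::lm.fit(x, ts)$residuals
  res <- as.matrix(res)
  dimnames(res) <- dimnames(ts)
  res
}

#' Ideal band-pass filter for node time series
#'
#' Applies a discrete-Fourier mask that keeps frequency bins with
#' `low <= f <= high` (inclusive) and always removes the zero-frequency
#' component, then inverts the transform. The ideal mask makes pass/stop
#' behaviour exactly testable and is idempotent.
#'
#' @param ts Timepoints x nodes matrix.
#' @param low,high Band edges in Hz; `0 <= low < high <= 1/(2 tr)`.
#' @param tr Sampling interval (repetition time), seconds.
#' @return Filtered real-valued matrix of the same shape.
#' @export
bandpass <- function(ts, low = 0.01, high = 0.08, tr = 2.0) {
  ts <- as.matrix(ts)
  n_t <- nrow(ts)
  if (n_t < 4) abort("Band-pass filtering needs at least 4 time points.")
  nyquist <- 1 / (2 * tr)
  if (!(low >= 0 && low < high)) abort("Require 0 <= low < high.")
  if (high > nyquist + 1e-12) {
    abort(paste0("High edge ", high, " Hz exceeds the Nyquist frequency ",
                 signif(nyquist, 6), " Hz at tr = ", tr, " s."))
  }
  f <- (seq_len(n_t) - 1) / (n_t * tr)
  f_folded <- pmin(f, 1 / tr - f)  # two-sided spectrum
  keep <- f_folded >= low - 1e-12 & f_folded <= high + 1e-12
  keep[1] <- FALSE  # zero frequency always removed
  yf <- stats::mvfft(ts)
  yf[!keep, ] <- 0+0i
  out <- Re(stats::mvfft(yf, inverse = TRUE)) / n_t
  dimnames(out) <- dimnames(ts)
  out
}

#' Full time-series cleaning pipeline
#'
#' Applies, in fixed order, linear detrending, optional nuisance regression,
#' and band-pass filtering.
#'
#' @inheritParams bandpass
#' @param confounds Optional nuisance regressor table (see
#'   [regress_confounds()]).
#' @return Cleaned timepoints x nodes matrix.
#' @export
preprocess_timeseries <- function(ts, confounds = NULL, low = 0.01,
                                  high = 0.08, tr = 2.0) {
  out <- detrend_linear(ts)
  if (!is.null(confounds)) out <- regress_confounds(out, confounds)
  bandpass(out, low = low, high = high, tr = tr)
}
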