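#' Functional connectivity from node time series
#'
#' Pearson correlation between every pair of node signals. Nodes with zero
#' variance get zero rows/columns (with a warning) rather than NaN so that
#' downstream proportional thresholding simply never selects them.
#'
#' @param ts Preprocessed timepoints x nodes matrix.
#' @return Symmetric correlation matrix with zero diagonal (class values in
#'   [-1, 1]).
#' @export
build_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) abort("Correlation needs at least 3 time points.")
  sds <- apply(ts, 2, stats::sd)
  degenerate <- sds == 0
  fc <- matrix(0, ncol(ts), ncol(ts))
  ok <- which(!degenerate)
  if (length(ok) >= 2) {
    fc[ok, ok] <- stats::cor(ts[, ok, drop = FALSE])
  }
  if (any(degenerate)) {
    warn(paste0("Zero-variance node(s) set to zero connectivity: ",
                paste(which(degenerate), collapse = ", ")))
  }
  diag(fc) <- 0
  labs <- colnames(ts) %||% default_labels(ncol(ts))
  dimnames(fc) <- list(labs, labs)
  fc
}

#' Structural connectivity from FA and fiber-count matrices
#'
#' The structural edge weight is the elementwise product of the fractional
#' anisotropy matrix (tract integrity, 0-1) and the fiber number matrix
#' (streamline count), so an edge carries weight only where both are
#' non-zero.
#'
#' @param fa Fractional anisotropy matrix.
#' @param fn Fiber count matrix, same shape and labels.
#' @return Symmetric non-negative structural connectivity matrix.
#' @export
build_sc <- function(fa, fn) {
  fa <- as.matrix(fa); fn <- as.matrix(fn)
  if (!all(dim(fa) == dim(fn))) {
    abort("FA and FN matrices must share the same shape.")
  }
  if (!is.null(dimnames(fa)) && !is.null(dimnames(fn)) &&
      !identical(dimnames(fa), dimnames(fn))) {
    abort("FA and FN matrices must share the same node labels.")
  }
  if (any((fa == 0) != (fn == 0))) {
    warn("FA and FN zero patterns differ; product zeroes the mismatches.")
  }
  sc <- fa * fn
  diag(sc) <- 0
  sc
}

#' Proportional-threshold sparsity grid
#'
#' @param start,stop,step Arithmetic sequence bounds and increment; the stop
#'   value is included when reached within 1e-9.
#' @return Numeric vector of class-free sparsity fractions (default grid has
#'   41 values, 0.05 to 0.45).
#' @export
#' @examples
#' length(sparsity_grid())  # 41
sparsity_grid <- function(start = 0.05, stop = 0.45, step = 0.01) {
  if (step <= 0) abort("`step` must be positive.")
  if (start <= 0 || stop >= 1 || start > stop) {
    abort("Require 0 < start <= stop < 1.")
  }
  if (start == stop) return(start)
  if (start + step > stop + 1e-9) {
    abort("`step` is larger than the grid range.")
  }
  k <- floor((stop - start) / step + 1e-9)
  start + step * (0:k)
}

#' Proportional thresholding of a connectivity matrix
#'
#' Keeps the `k = floor(s * N(N-1)/2 + 0.5)` strongest edges (round-half-up)
#' of a symmetric matrix and zeroes the rest; retained edges keep their
#' weights. Ties are broken deterministically by weight (descending) then by
#' node-pair index `(i, j)`, `i < j`, in row-major order, so edge sets are
#' nested across sparsities and platform independent. For functional
#' matrices, negative correlations are handled by `policy`: `"zero"` excludes
#' them from ranking and retention; `"absolute"` ranks by `|r|` and retains
#' `|r|` as the weight.
#'
#' @param mat Symmetric numeric matrix.
#' @param s Sparsity fraction in (0, 1).
#' @param policy Negative-weight policy, `"zero"` or `"absolute"`.
#' @return A `thresholded_network`: list with `weights` (matrix), `sparsity`,
#'   and `retained_edges`.
#' @export
threshold_proportional <- function(mat, s, policy = c("zero", "absolute")) {
  policy <- match.arg(policy)
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n != ncol(mat)) abort("Matrix must be square.")
  if (max(abs(mat - t(mat))) > 1e-8) abort("Matrix must be symmetric.")
  n_pairs <- n * (n - 1) / 2
  k <- floor(s * n_pairs + 0.5)
  if (k < 1) abort(paste0("Degenerate sparsity ", s, ": no edges retained."))

  ut <- which(upper.tri(mat))
  w <- mat[ut]
  ij <- arrayInd(ut, dim(mat))
  i <- pmin(ij[, 1], ij[, 2]); j <- pmax(ij[, 1], ij[, 2])
  if (policy == "zero") {
    rank_w <- w
    keep_w <- w
    eligible <- w > 0
  } else {
    rank_w <- abs(w)
    keep_w <- abs(w)
    eligible <- w != 0
  }
  cand <- which(eligible)
  ord <- cand[order(-rank_w[cand], i[cand], j[cand])]
  sel <- head(ord, k)

  out <- matrix(0, n, n, dimnames = dimnames(mat))
  out[cbind(i[sel], j[sel])] <- keep_w[sel]
  out[cbind(j[sel], i[sel])] <- keep_w[sel]
  structure(
    list(weights = out, sparsity = s, retained_edges = length(sel)),
    class = "thresholded_network"
  )
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat("<thresholded_network> ", nrow(x$weights), " nodes, sparsity ",
      x$sparsity, ", ", x$retained_edges, " edges retained\n", sep = "")
  invisible(x)
}

# Accept either a thresholded_network or a bare weighted adjacency matrix.
net_weights <- function(net) {
  if (inherits(net, "thresholded_network")) net$weights else as.matrix(net)
}
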