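#' Degree-preserving null ensemble for small-world normalization
#'
#' Each null network keeps the original binary topology's exact degree
#' sequence via Maslov-Sneppen double-edge swaps (`10 * |E|` rewiring trials)
#' and then redistributes the original weight multiset uniformly at random
#' over the rewired edges. The clustering coefficient and characteristic path
#' length of every null are recorded.
#'
#' @param net A `thresholded_network` or weight matrix with at least 2 edges.
#' @param n_null Number of null networks.
#' @param seed Optional integer seed for reproducible ensembles; when `NULL`
#'   the current RNG stream is used.
#' @return Tibble with one row per null: `null`, `Cp`, `Lp`.
#' @export
build_null_ensemble <- function(net, n_null, seed = NULL) {
  w <- net_weights(net)
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0)
  m <- length(ut)
  if (m < 2) abort("Null ensemble needs at least 2 edges.")
  if (n_null < 1) abort("`n_null` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)

  weights <- w[ut]
  ij <- arrayInd(ut, dim(w))
  g0 <- igraph::make_empty_graph(n, directed = FALSE)
  g0 <- igraph::add_edges(g0, as.vector(t(ij)))
  niter <- 10L * m

  cp <- numeric(n_null)
  lp <- numeric(n_null)
  wn <- matrix(0, n, n)
  for (b in seq_len(n_null)) {
    gr <- igraph::rewire(g0, igraph::keeping_degseq(niter = niter))
    wp <- sample(weights)
    el <- igraph::as_edgelist(gr, names = FALSE)
    wn[] <- 0
    wn[el] <- wp
    wn[el[, c(2, 1)]] <- wp
    d <- igraph::distances(gr, weights = 1 / wp)
    off <- d[row(d) != col(d)]
    finite <- is.finite(off)
    lp[b] <- if (any(finite)) mean(off[finite]) else 0
    cp[b] <- mean(onnela_clustering(wn))
  }
  tibble(null = seq_len(n_null), Cp = cp, Lp = lp)
}

#' Small-world normalization against a null ensemble
#'
#' gamma = Cp / mean(null Cp), lambda = Lp / mean(null Lp), and the
#' small-worldness ratio sigma = gamma / lambda. sigma > 1 indicates
#' small-world organization (clustering above, path length near, the random
#' benchmark). Zero null means yield `NA` with a message.
#'
#' @param global One-row tibble (or list) with `Cp` and `Lp` of the observed
#'   network, as from [compute_global()].
#' @param ensemble Null ensemble tibble from [build_null_ensemble()].
#' @return One-row tibble: `gamma`, `lambda`, `sigma`.
#' @export
normalize_small_world <- function(global, ensemble) {
  if (nrow(ensemble) < 1) abort("Null ensemble is empty.")
  cp_null <- mean(ensemble$Cp)
  lp_null <- mean(ensemble$Lp)
  if (cp_null <= 0 || lp_null <= 0) {
    inform("Zero null-ensemble means: small-world indices reported missing.")
    return(tibble(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_))
  }
  gamma <- global$Cp / cp_null
  lambda <- global$Lp / lp_null
  tibble(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' One-call small-world indices of a network
#'
#' Convenience wrapper: computes observed Cp and Lp, builds the null
#' ensemble, and returns observed and normalized indices together.
#'
#' @inheritParams build_null_ensemble
#' @return One-row tibble: `Cp`, `Lp`, `gamma`, `lambda`, `sigma`.
#' @export
small_world <- function(net, n_null = 100, seed = NULL) {
  glob <- compute_global(net, metrics = c("Cp", "Lp"))
  ens <- build_null_ensemble(net, n_null = n_null, seed = seed)
  dplyr::bind_cols(glob[, c("Cp", "Lp")], normalize_small_world(glob, ens))
}
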