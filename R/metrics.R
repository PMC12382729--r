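#' All-pairs shortest path lengths of a weighted network
#'
#' Edge lengths are reciprocals of edge weights (strong connections are
#' short), the standard convention for correlation- and streamline-weighted
#' brain networks. Unreachable pairs get `Inf`.
#'
#' @param net A `thresholded_network` or symmetric non-negative weight
#'   matrix.
#' @return Numeric node x node distance matrix with zero diagonal.
#' @export
shortest_path_lengths <- function(net) {
  w <- net_weights(net)
  if (any(w < 0)) abort("Negative edge weights are not supported.")
  g <- graph_from_wadj(w)
  d <- igraph::distances(g$graph, weights = g$lengths)
  dimnames(d) <- dimnames(w)
  d
}

# Build an igraph graph plus 1/weight edge lengths from a weight matrix.
graph_from_wadj <- function(w) {
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0)
  ij <- arrayInd(ut, dim(w))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(ij) > 0) {
    g <- igraph::add_edges(g, as.vector(t(ij)))
  }
  list(graph = g, weights = w[ut], lengths = 1 / w[ut])
}

# Onnela weighted clustering per node: geometric mean of triangle weights,
# weights normalized by the network maximum. Zero for degree < 2.
onnela_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx <= 0) return(numeric(n))
  a <- (w / mx)^(1/3)
  num <- rowSums((a %*% a) * a)  # diag(a %*% a %*% a), a symmetric
  k <- rowSums(w > 0)
  ci <- numeric(n)
  idx <- k >= 2
  ci[idx] <- num[idx] / (k[idx] * (k[idx] - 1))
  ci
}

# Global efficiency from a distance matrix: mean of 1/d over ordered pairs,
# 1/Inf = 0.
efficiency_from_dist <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# Local efficiency of every node: global efficiency of the subgraph induced
# by its neighbours (weights as-is); 0 for degree < 2.
local_efficiency_nodes <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  nb_list <- apply(w > 0, 1, which, simplify = FALSE)
  for (i in seq_len(n)) {
    nb <- nb_list[[i]]
    if (length(nb) < 2) next
    sub <- graph_from_wadj(w[nb, nb, drop = FALSE])
    out[i] <- efficiency_from_dist(
      igraph::distances(sub$graph, weights = sub$lengths)
    )
  }
  out
}

#' Global graph metrics of a weighted network
#'
#' Computes the four weighted global properties used throughout the sweep:
#' \describe{
#'   \item{Cp}{mean Onnela clustering coefficient (geometric-mean triangle
#'     weights, max-normalized per network);}
#'   \item{Lp}{characteristic path length — mean of finite off-diagonal
#'     shortest path lengths over reachable pairs (edge length = 1/weight);}
#'   \item{Eg}{global efficiency — mean of 1/distance over all ordered pairs
#'     with unreachable pairs contributing 0;}
#'   \item{Eloc}{local efficiency — mean over nodes of the global efficiency
#'     of each node's neighbour-induced subgraph.}
#' }
#' An empty network returns all zeros with a warning. The fraction of
#' disconnected node pairs is attached as the `disconnected` column so the
#' reachable-pairs Lp convention is auditable.
#'
#' @param net A `thresholded_network` or weight matrix.
#' @param metrics Character subset of `c("Cp", "Lp", "Eg", "Eloc")`; computing
#'   fewer metrics skips the corresponding work.
#' @return One-row tibble with the requested metrics plus `disconnected`.
#' @export
compute_global <- function(net, metrics = c("Cp", "Lp", "Eg", "Eloc")) {
  w <- net_weights(net)
  n <- nrow(w)
  if (n < 2) abort("Global metrics need at least 2 nodes.")
  metrics <- match.arg(metrics, c("Cp", "Lp", "Eg", "Eloc"),
                       several.ok = TRUE)
  out <- list()
  if (all(w == 0)) {
    warn("Empty edge set: all global metrics reported as 0.")
    for (m in metrics) out[[m]] <- 0
    out$disconnected <- 1
    return(as_tibble(out))
  }
  need_dist <- any(c("Lp", "Eg") %in% metrics)
  if (need_dist) {
    d <- shortest_path_lengths(w)
    off <- d[row(d) != col(d)]
    finite <- is.finite(off)
    if ("Lp" %in% metrics) {
      out$Lp <- if (any(finite)) mean(off[finite]) else 0
    }
    if ("Eg" %in% metrics) out$Eg <- efficiency_from_dist(d)
    out$disconnected <- mean(!finite)
  }
  if ("Cp" %in% metrics) out$Cp <- mean(onnela_clustering(w))
  if ("Eloc" %in% metrics) out$Eloc <- mean(local_efficiency_nodes(w))
  as_tibble(out)[, c(metrics, if (need_dist) "disconnected")]
}

#' Nodal graph metrics of a weighted network
#'
#' Per-node properties:
#' \describe{
#'   \item{Dc}{degree centrality as node strength, the sum of incident edge
#'     weights;}
#'   \item{Bc}{betweenness centrality (unnormalized shortest-path counts) on
#'     1/weight edge lengths;}
#'   \item{Ne}{nodal efficiency, the mean of 1/distance to every other node;}
#'   \item{Nle}{nodal local efficiency, the global efficiency of the
#'     neighbour-induced subgraph;}
#'   \item{NCp}{nodal Onnela clustering coefficient.}
#' }
#'
#' @param net A `thresholded_network` or weight matrix.
#' @return Tibble with one row per node: `node`, `label`, `Dc`, `Bc`, `Ne`,
#'   `Nle`, `NCp`.
#' @export
compute_nodal <- function(net) {
  w <- net_weights(net)
  n <- nrow(w)
  if (n < 2) abort("Nodal metrics need at least 2 nodes.")
  labs <- rownames(w) %||% default_labels(n)
  if (all(w == 0)) {
    warn("Empty edge set: all nodal metrics reported as 0.")
    return(tibble(node = seq_len(n), label = labs, Dc = 0, Bc = 0, Ne = 0,
                  Nle = 0, NCp = 0))
  }
  g <- graph_from_wadj(w)
  d <- igraph::distances(g$graph, weights = g$lengths)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  tibble(
    node = seq_len(n),
    label = labs,
    Dc = rowSums(w),
    Bc = as.numeric(igraph::betweenness(g$graph, weights = g$lengths,
                                        normalized = FALSE)),
    Ne = rowSums(inv) / (n - 1),
    Nle = local_efficiency_nodes(w),
    NCp = onnela_clustering(w)
  )
}

#' Integrate a metric curve over the sparsity grid
#'
#' Summarizes a per-threshold metric curve into a single threshold-free value
#' per subject — the area under the curve across the sparsity grid.
#'
#' @param curve Numeric metric values, one per grid point.
#' @param grid Sparsity grid (strictly increasing, same length as `curve`).
#' @param rule `"trapezoid"` (default) or `"rectangle"` (step x sum, the
#'   historical step-sum convention).
#' @return Scalar AUC.
#' @export
#' @examples
#' integrate_auc(rep(0.5, 41), sparsity_grid())  # 0.2
integrate_auc <- function(curve, grid, rule = c("trapezoid", "rectangle")) {
  rule <- match.arg(rule)
  if (length(curve) != length(grid)) {
    abort("Curve and grid must have the same length.")
  }
  if (length(grid) < 2) abort("AUC needs at least 2 grid points.")
  if (any(diff(grid) <= 0)) abort("Grid must be strictly increasing.")
  bad <- which(!is.finite(curve))
  if (length(bad) > 0) {
    abort(paste0("Non-finite metric value at sparsity ", grid[bad[1]], "."))
  }
  if (rule == "trapezoid") {
    sum(diff(grid) * (head(curve, -1) + tail(curve, -1)) / 2)
  } else {
    step <- grid[2] - grid[1]
    step * sum(curve)
  }
}
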