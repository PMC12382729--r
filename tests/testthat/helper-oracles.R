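# Independent brute-force reference implementations used to validate the
# graph metrics. Deliberately naive: scalar-loop Floyd-Warshall distances,
# exhaustive triangle enumeration, and shortest-path counting over
# predecessor sets. Nothing here calls igraph or the package internals.

oracle_fw <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Shortest-path counts sigma[s, t], processing targets in distance order so
# every predecessor count is final before it is used.
oracle_path_counts <- function(w, d) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- Inf
  sig <- matrix(0, n, n)
  tol <- 1e-9
  for (s in seq_len(n)) {
    sig[s, s] <- 1
    for (t in order(d[s, ])) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(is.finite(len[, t]) &
                       abs(d[s, ] + len[, t] - d[s, t]) < tol)
      sig[s, t] <- sum(sig[s, preds])
    }
  }
  sig
}

oracle_betweenness <- function(w) {
  d <- oracle_fw(w)
  sig <- oracle_path_counts(w, d)
  n <- nrow(w)
  tol <- 1e-9
  bc <- numeric(n)
  for (i in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in seq.int(s + 1, n)) {
      if (s == i || t == i || !is.finite(d[s, t]) || sig[s, t] == 0) next
      if (abs(d[s, i] + d[i, t] - d[s, t]) < tol) {
        bc[i] <- bc[i] + sig[s, i] * sig[i, t] / sig[s, t]
      }
    }
  }
  bc
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  ci <- numeric(n)
  if (mx <= 0) return(ci)
  a <- (w / mx)^(1 / 3)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tot <- 0
    for (j in nb) for (h in nb) {
      if (j != h) tot <- tot + a[i, j] * a[j, h] * a[h, i]
    }
    ci[i] <- tot / (k * (k - 1))
  }
  ci
}

oracle_efficiency <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  vals <- 1 / d[row(d) != col(d)]
  vals[!is.finite(vals)] <- 0
  mean(vals)
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    out[i] <- oracle_efficiency(oracle_fw(w[nb, nb, drop = FALSE]))
  }
  out
}

oracle_global <- function(w) {
  d <- oracle_fw(w)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  list(
    Cp = mean(oracle_clustering(w)),
    Lp = if (any(finite)) mean(off[finite]) else 0,
    Eg = oracle_efficiency(d),
    Eloc = mean(oracle_local_efficiency(w))
  )
}

oracle_nodal <- function(w) {
  d <- oracle_fw(w)
  n <- nrow(w)
  ne <- vapply(seq_len(n), function(i) {
    vals <- 1 / d[i, -i]
    vals[!is.finite(vals)] <- 0
    mean(vals)
  }, numeric(1))
  list(
    Dc = rowSums(w),
    Bc = oracle_betweenness(w),
    Ne = ne,
    Nle = oracle_local_efficiency(w),
    NCp = oracle_clustering(w)
  )
}

# Random weighted graph; power-of-two weights give exactly representable
# path-length sums so tie handling is consistent across implementations.
rand_wgraph <- function(n, p = 0.5, pow2 = TRUE) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- ut[runif(length(ut)) < p]
  vals <- if (pow2) {
    2^sample(-2:2, length(on), replace = TRUE)
  } else {
    runif(length(on), 0.5, 2)
  }
  w[on] <- vals
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  w
}

# Simple named weight matrix from an edge list for hand-built examples.
wadj <- function(n, edges, weights = 1) {
  w <- matrix(0, n, n)
  e <- matrix(edges, ncol = 2, byrow = TRUE)
  w[e] <- weights
  w[e[, c(2, 1)]] <- weights
  w
}
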