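# Brute-force reference implementations, independent of the package (and of
# igraph): Floyd-Warshall distances, direct neighbour-pair clustering, and
# betweenness by exhaustive shortest-path enumeration. Feasible for the
# small graphs the oracle suites use (<= 12 nodes).

# Edge-length matrix: 1/weight on edges (1 for binary), Inf off-edge.
oracle_lengths <- function(W) {
  n <- nrow(W)
  L <- matrix(Inf, n, n)
  L[W > 0] <- 1 / W[W > 0]
  diag(L) <- 0
  L
}

oracle_distances <- function(W) {
  D <- oracle_lengths(W)
  n <- nrow(D)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Per-node clustering: direct loop over neighbour pairs. Binary graphs use
# the connected-fraction form; weighted graphs the Onnela geometric mean
# with weights scaled by the network maximum.
oracle_clustering <- function(W) {
  n <- nrow(W)
  binary <- all(W %in% c(0, 1))
  wmax <- max(W)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tot <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      u <- nb[a]; v <- nb[b]
      if (W[u, v] > 0) {
        tot <- tot + if (binary) 1 else
          (W[i, u] / wmax * W[i, v] / wmax * W[u, v] / wmax)^(1 / 3)
      }
    }
    ci[i] <- 2 * tot / (k * (k - 1))
  }
  ci
}

oracle_lp <- function(W) {
  D <- oracle_distances(W)
  d <- D[upper.tri(D)]
  fin <- is.finite(d)
  if (!any(fin)) return(NA_real_)
  mean(d[fin])
}

oracle_eg <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- oracle_distances(W)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_eloc <- function(W) {
  n <- nrow(W)
  el <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    el[i] <- oracle_eg(W[nb, nb, drop = FALSE])
  }
  mean(el)
}

# All shortest paths s -> t as node sequences, by recursive descent on the
# distance matrix.
oracle_shortest_paths <- function(L, D, s, t, tol = 1e-9) {
  rec <- function(u) {
    if (u == t) return(list(u))
    out <- list()
    for (v in which(is.finite(L[u, ]) & seq_len(ncol(L)) != u)) {
      if (abs(L[u, v] + D[v, t] - D[u, t]) < tol) {
        for (p in rec(v)) out[[length(out) + 1L]] <- c(u, p)
      }
    }
    out
  }
  rec(s)
}

# Pair-fractional betweenness, endpoints excluded.
oracle_betweenness <- function(W) {
  n <- nrow(W)
  L <- oracle_lengths(W)
  D <- oracle_distances(W)
  B <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    paths <- oracle_shortest_paths(L, D, s, t)
    cnt <- numeric(n)
    for (p in paths) {
      mid <- p[-c(1, length(p))]
      cnt[mid] <- cnt[mid] + 1
    }
    B <- B + cnt / length(paths)
  }
  B
}

oracle_all <- function(W) {
  list(clustering = oracle_clustering(W), Lp = oracle_lp(W),
       Eg = oracle_eg(W), Eloc = oracle_eloc(W),
       betweenness = oracle_betweenness(W))
}

# Compare package metrics against the oracle on one dense weight matrix.
expect_matches_oracle <- function(W, tol = 1e-10) {
  mode <- if (all(W %in% c(0, 1))) "binary" else "weighted"
  tg <- dknet::thresholded_graph_from_dense(W, mode = mode)
  o <- oracle_all(W)
  expect_equal(unname(clustering_coefficient(tg)$node), o$clustering,
               tolerance = tol)
  if (!is.na(o$Lp))
    expect_equal(as.numeric(characteristic_path_length(tg)), o$Lp,
                 tolerance = tol)
  ef <- efficiency(tg)
  expect_equal(ef$Eg, o$Eg, tolerance = tol)
  expect_equal(ef$Eloc, o$Eloc, tolerance = tol)
  expect_equal(unname(betweenness_centrality(tg)$node), o$betweenness,
               tolerance = 1e-8)
  invisible(TRUE)
}

# Random simple graph as a dense matrix; weighted draws weights in
# [0.5, 2].
random_dense_graph <- function(n, p = NULL, weighted = FALSE) {
  if (is.null(p)) p <- runif(1, 0.2, 0.8)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- ut[runif(length(ut)) < p]
  W[on] <- if (weighted) runif(length(on), 0.5, 2) else 1
  W + t(W)
}

# All non-isomorphic simple graphs on n nodes (labeled enumeration plus
# canonical-form filtering); practical for n <= 6.
enumerate_nonisomorphic <- function(n) {
  m <- n * (n - 1) / 2
  ut <- which(upper.tri(matrix(0, n, n)))
  seen <- new.env(hash = TRUE)
  out <- list()
  for (mask in 0:(2^m - 1)) {
    bits <- bitwAnd(bitwShiftR(mask, 0:(m - 1)), 1L) == 1L
    W <- matrix(0, n, n)
    W[ut[bits]] <- 1
    W <- W + t(W)
    g <- igraph::graph_from_adjacency_matrix(W, "undirected")
    cp <- igraph::canonical_permutation(g)$labeling
    gc <- igraph::permute(g, cp)
    el <- igraph::as_edgelist(gc, names = FALSE)
    key <- paste0("k", paste(el[order(el[, 1], el[, 2]), ], collapse = ","))
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <- W
    }
  }
  out
}
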