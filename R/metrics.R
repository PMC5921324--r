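# Nodal and network topology metrics, and small-worldness against matched
# null ensembles.
#
# Conventions (stated in output metadata where they matter):
# * weighted graphs use distance = 1/weight for all path-based metrics;
# * characteristic path length averages over finite (connected) pairs only,
#   reporting the number of excluded infinite pairs;
# * weighted clustering uses the Onnela geometric-mean form by default.

# Per-node clustering from a dense weight matrix. Binary graphs: fraction of
# a node's neighbour pairs that are connected. Weighted: Onnela form,
# C_i = sum_(j,h) (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1)), w' = w/max(w),
# or the plain topological form ignoring weights.
local_clustering_dense <- function(W, method = c("onnela", "binary")) {
  method <- match.arg(method)
  k <- rowSums(W > 0)
  if (max(W) == 0) return(rep(0, nrow(W)))
  if (method == "binary" || all(W %in% c(0, 1))) {
    A <- (W > 0) + 0
    cyc <- diag(A %*% A %*% A)
    return(ifelse(k >= 2, cyc / (k * (k - 1)), 0))
  }
  Wh <- (W / max(W))^(1 / 3)
  cyc <- diag(Wh %*% Wh %*% Wh)
  ifelse(k >= 2, cyc / (k * (k - 1)), 0)
}

# All-pairs shortest-path distances of a thresholded graph (1/weight for
# weighted graphs).
graph_distances <- function(tg) {
  g <- as_igraph(tg)
  w <- if (is.null(tg$weights)) NULL else {
    if (any(tg$weights <= 0))
      stop("weighted path metrics need strictly positive edge weights")
    1 / igraph::E(g)$weight
  }
  igraph::distances(g, weights = w)
}

#' Clustering coefficient
#'
#' Per-node clustering (the fraction of a node's neighbour pairs that are
#' themselves connected; Onnela geometric-mean form for weighted graphs)
#' and their unweighted mean Cp. Nodes with degree < 2 score 0.
#'
#' @param tg a [thresholded_graph()].
#' @param weighted_method `"onnela"` (default, geometric-mean weights) or
#'   `"binary"` (topology only) for weighted graphs.
#' @return list with `node` (per-node values) and `Cp` (mean).
#' @examples
#' tri <- thresholded_graph(rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4)), n_nodes = 4)
#' clustering_coefficient(tri)$Cp   # 7/12
#' @export
clustering_coefficient <- function(tg, weighted_method = c("onnela", "binary")) {
  stopifnot(inherits(tg, "thresholded_graph"))
  ci <- local_clustering_dense(adjacency_of(tg), match.arg(weighted_method))
  names(ci) <- tg$labels
  list(node = ci, Cp = mean(ci))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all connected (finite) node pairs.
#' Weighted graphs use distance = 1/weight. Disconnected pairs are excluded
#' and counted in the `n_infinite_pairs` attribute.
#'
#' @param tg a [thresholded_graph()].
#' @return Lp as a numeric scalar with attribute `n_infinite_pairs`.
#' @export
characteristic_path_length <- function(tg) {
  d <- graph_distances(tg)
  d <- d[upper.tri(d)]
  fin <- is.finite(d)
  if (!any(fin)) stop("empty path set: no finite node pair")
  structure(mean(d[fin]), n_infinite_pairs = sum(!fin))
}

#' Global and local efficiency
#'
#' Global efficiency Eg is the mean of 1/d(i, j) over all node pairs
#' (1/Inf = 0). Local efficiency Eloc is the mean, over nodes, of the
#' global efficiency of the subgraph induced by each node's neighbours
#' (0 for degree < 2). Weighted graphs use distance = 1/weight.
#'
#' @param tg a [thresholded_graph()].
#' @return list with `Eg`, `Eloc` and per-node `node_Eloc`.
#' @export
efficiency <- function(tg) {
  d <- graph_distances(tg)
  n <- tg$n_nodes
  Eg <- if (n < 2) 0 else {
    inv <- 1 / d
    diag(inv) <- 0
    sum(inv) / (n * (n - 1))
  }
  W <- adjacency_of(tg)
  node_eloc <- vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- W[nb, nb, drop = FALSE]
    subg <- thresholded_graph_from_dense(sub, mode = tg$mode)
    dsub <- graph_distances(subg)
    inv <- 1 / dsub
    diag(inv) <- 0
    sum(inv) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  names(node_eloc) <- tg$labels
  list(Eg = Eg, Eloc = mean(node_eloc), node_Eloc = node_eloc)
}

#' Build a thresholded graph directly from a dense weight matrix
#'
#' Every nonzero upper-triangle entry becomes an edge; weighted mode keeps
#' the entries as edge weights. Useful for graphs whose topology is already
#' fixed (e.g. tract-defined white-matter networks).
#'
#' @param W square symmetric numeric matrix, zero diagonal.
#' @param mode `"binary"` or `"weighted"`.
#' @param sparsity optional sparsity annotation.
#' @return a [thresholded_graph()].
#' @export
thresholded_graph_from_dense <- function(W, mode = c("binary", "weighted"),
                                         sparsity = NA_real_) {
  mode <- match.arg(mode)
  ut <- which(upper.tri(W) & W != 0)
  ij <- arrayInd(ut, dim(W))
  thresholded_graph(ij, weights = if (mode == "weighted") W[ut] else NULL,
                    n_nodes = nrow(W),
                    labels = colnames(W) %||% default_regions(nrow(W)),
                    sparsity = sparsity, mode = mode)
}

#' Betweenness centrality
#'
#' Unnormalised pair-fractional betweenness: each source-target pair
#' contributes the fraction of its shortest paths passing through the node,
#' endpoints excluded. Weighted graphs use distance = 1/weight.
#'
#' @param tg a [thresholded_graph()].
#' @return list with `node` (per-node Bi) and `B` (mean betweenness).
#' @export
betweenness_centrality <- function(tg) {
  g <- as_igraph(tg)
  w <- if (is.null(tg$weights)) NULL else 1 / igraph::E(g)$weight
  bi <- igraph::betweenness(g, weights = w, directed = FALSE)
  names(bi) <- tg$labels
  list(node = bi, B = mean(bi))
}

#' All topology metrics of one network
#'
#' Convenience bundle: per-node clustering/betweenness/degree and the
#' network-level Cp, Lp, Eg, Eloc and mean betweenness.
#'
#' @param tg a [thresholded_graph()].
#' @return an object of class `network_metrics`.
#' @export
network_metrics <- function(tg) {
  cc <- clustering_coefficient(tg)
  lp <- characteristic_path_length(tg)
  ef <- efficiency(tg)
  bw <- betweenness_centrality(tg)
  deg <- rowSums(adjacency_of(tg) > 0)
  structure(list(
    Cp = cc$Cp, Lp = as.numeric(lp), Eg = ef$Eg, Eloc = ef$Eloc, B = bw$B,
    node_clustering = cc$node, node_betweenness = bw$node,
    node_Eloc = ef$node_Eloc, degree = deg,
    n_infinite_pairs = attr(lp, "n_infinite_pairs"),
    sparsity = tg$sparsity, mode = tg$mode
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("<network_metrics> Cp %.4f  Lp %.4f  Eg %.4f  Eloc %.4f  B %.3f\n",
              x$Cp, x$Lp, x$Eg, x$Eloc, x$B))
  if (x$n_infinite_pairs > 0)
    cat(sprintf("  (%d disconnected pairs excluded from Lp)\n", x$n_infinite_pairs))
  invisible(x)
}

#' Matched null-network ensemble
#'
#' Generates `n_rand` null graphs matched to the input. The default model
#' preserves the exact degree sequence through double-edge-swap rewiring
#' (10 x edge-count swap attempts); the `"erdos_renyi"` option only
#' preserves node and edge counts. Weighted graphs keep their weight
#' multiset, shuffled across the rewired edges. If no valid swap exists
#' (e.g. a triangle) the ensemble consists of copies of the input and a
#' warning is emitted.
#'
#' @param tg a [thresholded_graph()].
#' @param n_rand ensemble size (default 100).
#' @param seed RNG seed for the ensemble.
#' @param model `"degree_preserving"` (default) or `"erdos_renyi"`.
#' @return list of [thresholded_graph()] objects.
#' @export
rewire_null <- function(tg, n_rand = 100, seed = 1,
                        model = c("degree_preserving", "erdos_renyi")) {
  model <- match.arg(model)
  stopifnot(inherits(tg, "thresholded_graph"))
  if (nrow(tg$edges) < 2) stop("need at least 2 edges to rewire")
  g <- as_igraph(tg)
  m <- nrow(tg$edges)
  nulls <- with_seed(seed, lapply(seq_len(n_rand), function(r) {
    gn <- if (model == "degree_preserving") {
      igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = 10 * m))
    } else {
      igraph::sample_gnm(tg$n_nodes, m)
    }
    el <- igraph::as_edgelist(gn, names = FALSE)
    wts <- if (is.null(tg$weights)) NULL else sample(tg$weights)
    thresholded_graph(el, weights = wts, n_nodes = tg$n_nodes,
                      labels = tg$labels, sparsity = tg$sparsity,
                      mode = tg$mode)
  }))
  if (model == "degree_preserving") {
    key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]),
                             sep = "-", collapse = ";")
    k0 <- key(tg$edges)
    if (all(vapply(nulls, function(x) identical(key(x$edges), k0), logical(1))))
      warning("no valid degree-preserving swap found; ensemble is copies of the input")
  }
  nulls
}

#' Small-worldness against a matched null ensemble
#'
#' Computes Cp and Lp of the network and of `n_rand` matched null networks,
#' then gamma = Cp/mean(Cprand), lambda = Lp/mean(Lprand), and
#' sigma = gamma/lambda. A network is classified small-world when
#' sigma > 1; the strict criterion (gamma > 1 and |lambda - 1| within
#' `lambda_tol`) is also reported.
#'
#' @param tg a [thresholded_graph()].
#' @param n_rand null-ensemble size (default 100).
#' @param seed RNG seed for the null ensemble.
#' @param null_model passed to [rewire_null()].
#' @param lambda_tol tolerance on |lambda - 1| for the strict criterion
#'   (default 0.25).
#' @return an object of class `small_world_result` with fields `Cp`, `Lp`,
#'   `Cprand`, `Lprand`, `gamma`, `lambda`, `sigma`, `is_small_world`,
#'   `strict_small_world`, `evaluable`, `n_rand`, `seed`.
#' @examples
#' cm <- connectivity_matrix(symmetrize0(matrix(runif(900), 30)),
#'                           weight_kind = "FA", level = "group")
#' sw <- small_worldness(threshold_by_sparsity(cm, 0.2), n_rand = 10, seed = 1)
#' sw$sigma == sw$gamma / sw$lambda
#' @export
small_worldness <- function(tg, n_rand = 100, seed = 1,
                            null_model = c("degree_preserving", "erdos_renyi"),
                            lambda_tol = 0.25) {
  null_model <- match.arg(null_model)
  if (nrow(tg$edges) < 1) stop("graph has no edges")
  Cp <- clustering_coefficient(tg)$Cp
  Lp <- as.numeric(characteristic_path_length(tg))
  nulls <- rewire_null(tg, n_rand = n_rand, seed = seed, model = null_model)
  Cprand <- mean(vapply(nulls, function(x) clustering_coefficient(x)$Cp, numeric(1)))
  Lprand <- mean(vapply(nulls, function(x)
    as.numeric(characteristic_path_length(x)), numeric(1)))
  evaluable <- Cprand > 0 && Lprand > 0 && Lp > 0
  gamma <- if (evaluable) Cp / Cprand else NA_real_
  lambda <- if (evaluable) Lp / Lprand else NA_real_
  sigma <- if (evaluable) gamma / lambda else NA_real_
  structure(list(
    Cp = Cp, Lp = Lp, Cprand = Cprand, Lprand = Lprand,
    gamma = gamma, lambda = lambda, sigma = sigma,
    is_small_world = isTRUE(sigma > 1),
    strict_small_world = isTRUE(gamma > 1 && abs(lambda - 1) <= lambda_tol),
    evaluable = evaluable, n_rand = n_rand, seed = seed,
    null_model = null_model, sparsity = tg$sparsity, mode = tg$mode
  ), class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf(
    "<small_world_result> gamma %.3f  lambda %.3f  sigma %.3f  (%s, n_rand %d)\n",
    x$gamma, x$lambda, x$sigma,
    if (x$is_small_world) "small-world" else "not small-world", x$n_rand))
  invisible(x)
}
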