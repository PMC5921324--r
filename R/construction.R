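# Network construction: regional metric tables -> correlation matrices,
# tract-derived matrices -> masked edge layers, and sparsity thresholding.

#' Regional metric table
#'
#' A subjects-by-regions table of one positive diffusion/kurtosis metric,
#' with subject identifiers and a group label per subject.
#'
#' @param values numeric matrix, subjects in rows, regions in columns.
#' @param subject_ids character vector, one per row.
#' @param group character/factor vector, one label per row.
#' @param regions character vector of region labels, one per column.
#' @param metric metric name (e.g. `"MK"`).
#' @return an object of class `regional_metric_table`.
#' @export
regional_metric_table <- function(values, subject_ids = NULL, group = NULL,
                                  regions = NULL, metric = "metric") {
  values <- as.matrix(values)
  if (is.null(regions)) regions <- colnames(values) %||% default_regions(ncol(values))
  if (is.null(subject_ids)) subject_ids <- rownames(values) %||% sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(group)) group <- rep("all", nrow(values))
  if (anyDuplicated(regions)) {
    stop("duplicate region labels: ",
         paste(unique(regions[duplicated(regions)]), collapse = ", "))
  }
  if (length(regions) != ncol(values) || length(subject_ids) != nrow(values) ||
      length(group) != nrow(values))
    stop("dimension mismatch between values, subject_ids, group and regions")
  if (any(!is.finite(values)))
    stop("regional metric values must all be finite")
  dimnames(values) <- list(subject_ids, regions)
  structure(list(values = values, subject_ids = subject_ids,
                 group = as.character(group), regions = regions,
                 metric = metric),
            class = "regional_metric_table")
}

#' @export
print.regional_metric_table <- function(x, ...) {
  tab <- table(x$group)
  cat(sprintf("<regional_metric_table> %s: %d subjects x %d regions (%s)\n",
              x$metric, nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Connectivity matrix
#'
#' A symmetric region-by-region weighted matrix with zero diagonal, either a
#' group-level correlation matrix or a subject-level tract-derived matrix.
#'
#' @param values square numeric matrix.
#' @param regions region labels.
#' @param weight_kind one of `"correlation"`, `"FN"`, `"length"`, or a
#'   diffusion/kurtosis metric name.
#' @param level `"group"` or `"subject"`.
#' @return an object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, regions = NULL,
                                weight_kind = "correlation",
                                level = c("group", "subject")) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (is.null(regions)) regions <- colnames(values) %||% default_regions(ncol(values))
  if (length(regions) != ncol(values)) stop("region labels do not match matrix size")
  if (max(abs(values - t(values))) > 1e-8) stop("connectivity matrix must be symmetric")
  values <- symmetrize0(values)
  if (weight_kind == "correlation" && max(abs(values)) > 1 + 1e-8)
    stop("correlation entries must lie in [-1, 1]")
  if (weight_kind == "FN") {
    if (any(values < 0) || any(values != round(values)))
      stop("FN entries must be nonnegative integers")
  }
  dimnames(values) <- list(regions, regions)
  structure(list(values = values, regions = regions,
                 weight_kind = weight_kind, level = level),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, weight: %s, level: %s\n",
              nrow(x$values), ncol(x$values), x$weight_kind, x$level))
  invisible(x)
}

#' Grey-matter correlation network from a regional metric table
#'
#' Entry (i, j) is the Pearson correlation, across subjects, between the
#' regional values of regions i and j; the diagonal is forced to zero. A
#' constant region column has undefined correlations; these are set to 0
#' with a warning naming the region.
#'
#' @param table a [regional_metric_table()] (typically one group).
#' @return a group-level [connectivity_matrix()] of kind `"correlation"`.
#' @examples
#' tab <- regional_metric_table(matrix(rexp(30), 10, 3), metric = "MK")
#' gm_correlation_matrix(tab)
#' @export
gm_correlation_matrix <- function(table) {
  stopifnot(inherits(table, "regional_metric_table"))
  X <- table$values
  if (nrow(X) < 3) stop("need at least 3 subjects to correlate regions")
  if (ncol(X) < 2) stop("need at least 2 regions")
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning("constant region column(s), correlations set to 0: ",
            paste(table$regions[const], collapse = ", "))
  }
  C <- suppressWarnings(stats::cor(X))
  C[const, ] <- 0
  C[, const] <- 0
  connectivity_matrix(symmetrize0(C), table$regions,
                      weight_kind = "correlation", level = "group")
}

#' Mask white-matter metric layers to the tract-defined edge set
#'
#' An edge exists where the fiber-number matrix has `FN >= fn_min`; every
#' per-edge metric layer (and FN itself) is masked to that edge set, so all
#' layers share one topology.
#'
#' @param fn a [connectivity_matrix()] of kind `"FN"`.
#' @param per_edge_metrics named list of [connectivity_matrix()] layers.
#' @param fn_min minimum streamline count for an edge to exist (default 1).
#' @return named list of masked [connectivity_matrix()] objects, with the
#'   masked `FN` layer first.
#' @export
wm_edge_matrices <- function(fn, per_edge_metrics = list(), fn_min = 1) {
  stopifnot(inherits(fn, "connectivity_matrix"), fn$weight_kind == "FN")
  for (nm in names(per_edge_metrics)) {
    m <- per_edge_metrics[[nm]]
    if (!inherits(m, "connectivity_matrix") ||
        !identical(m$regions, fn$regions)) {
      bad <- if (inherits(m, "connectivity_matrix"))
        paste(setdiff(union(m$regions, fn$regions),
                      intersect(m$regions, fn$regions)), collapse = ", ")
      else "not a connectivity_matrix"
      stop(sprintf("layer '%s' does not match the FN node labels: %s", nm, bad))
    }
  }
  mask <- fn$values >= fn_min
  out <- list(FN = connectivity_matrix(fn$values * mask, fn$regions,
                                       weight_kind = "FN", level = fn$level))
  for (nm in names(per_edge_metrics)) {
    m <- per_edge_metrics[[nm]]
    out[[nm]] <- connectivity_matrix(m$values * mask, m$regions,
                                     weight_kind = m$weight_kind,
                                     level = m$level)
  }
  out
}

# Deterministic ranking of the upper-triangle entries of a connectivity
# matrix: decreasing ranking value (|r| for correlations, raw weight
# otherwise), ties broken by lexicographic (i, j) node order.
edge_ranking <- function(cm, rank = c("abs", "positive")) {
  rank <- match.arg(rank)
  V <- cm$values
  ut <- which(upper.tri(V))
  ij <- arrayInd(ut, dim(V))
  w <- V[ut]
  rv <- if (cm$weight_kind == "correlation") {
    if (rank == "positive") pmax(w, 0) else abs(w)
  } else w
  o <- order(-rv, ij[, 1], ij[, 2])
  list(idx = ut[o], i = ij[o, 1], j = ij[o, 2], value = rv[o])
}

#' Threshold a connectivity matrix at a target sparsity
#'
#' Retains exactly `K = floor(sparsity * N(N-1)/2)` edges with the largest
#' ranking value: `|r|` for correlation matrices (configurable to
#' positive-only), the raw weight otherwise. Ties at the cutoff are broken
#' by lexicographic node order, making the edge set reproducible. Binary
#' mode discards weights; weighted mode carries the ranking magnitudes as
#' positive edge weights.
#'
#' @param cm a [connectivity_matrix()].
#' @param sparsity fraction of possible edges to retain, in (0, 1].
#' @param mode `"binary"` or `"weighted"`.
#' @param rank `"abs"` (default) or `"positive"`: how negative correlations
#'   are ranked.
#' @return an object of class `thresholded_graph`.
#' @examples
#' cm <- connectivity_matrix(symmetrize0(matrix(runif(100), 10)), level = "group",
#'                           weight_kind = "FA")
#' threshold_by_sparsity(cm, 0.2)
#' @export
threshold_by_sparsity <- function(cm, sparsity, mode = c("binary", "weighted"),
                                  rank = c("abs", "positive")) {
  mode <- match.arg(mode)
  rank <- match.arg(rank)
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must lie in (0, 1]")
  N <- length(cm$regions)
  K <- floor(sparsity * N * (N - 1) / 2)
  if (K < 1) stop(sprintf("sparsity too low for N: %g keeps no edge at N=%d",
                          sparsity, N))
  rk <- edge_ranking(cm, rank)
  sel <- seq_len(K)
  thresholded_graph(
    edges = cbind(rk$i[sel], rk$j[sel]),
    weights = if (mode == "weighted") rk$value[sel] else NULL,
    n_nodes = N, labels = cm$regions, sparsity = sparsity, mode = mode
  )
}

#' Thresholded graph
#'
#' An undirected simple graph produced by sparsity thresholding: node
#' labels, an edge list, optional positive edge weights, and the sparsity
#' it was cut at.
#'
#' @param edges two-column integer matrix of node indices.
#' @param weights optional positive edge weights (weighted mode).
#' @param n_nodes number of nodes.
#' @param labels node labels.
#' @param sparsity the sparsity level, in (0, 1].
#' @param mode `"binary"` or `"weighted"`.
#' @return an object of class `thresholded_graph`.
#' @export
thresholded_graph <- function(edges, weights = NULL, n_nodes,
                              labels = default_regions(n_nodes),
                              sparsity = NA_real_,
                              mode = if (is.null(weights)) "binary" else "weighted") {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) && any(edges[, 1] == edges[, 2]))
    stop("self-loops are not allowed")
  if (!is.null(weights) && length(weights) != nrow(edges))
    stop("weights must match the edge list")
  structure(list(edges = edges, weights = weights, n_nodes = as.integer(n_nodes),
                 labels = labels, sparsity = sparsity, mode = mode),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("<thresholded_graph> %d nodes, %d edges (%s%s)\n",
              x$n_nodes, nrow(x$edges), x$mode,
              if (is.na(x$sparsity)) "" else sprintf(", sparsity %.2f", x$sparsity)))
  invisible(x)
}

#' Convert a thresholded graph to an igraph object
#'
#' @param tg a [thresholded_graph()].
#' @return an undirected `igraph` graph; weighted graphs carry an edge
#'   attribute `weight`.
#' @export
as_igraph <- function(tg) {
  stopifnot(inherits(tg, "thresholded_graph"))
  g <- igraph::make_empty_graph(tg$n_nodes, directed = FALSE)
  if (nrow(tg$edges))
    g <- igraph::add_edges(g, t(tg$edges))
  igraph::V(g)$name <- tg$labels
  if (!is.null(tg$weights)) igraph::E(g)$weight <- tg$weights
  g
}

#' Dense adjacency / weight matrix of a thresholded graph
#'
#' Binary graphs give a 0/1 adjacency; weighted graphs place the edge
#' weights.
#'
#' @param tg a [thresholded_graph()].
#' @return an N x N symmetric matrix with region dimnames.
#' @export
adjacency_of <- function(tg) {
  A <- matrix(0, tg$n_nodes, tg$n_nodes)
  if (nrow(tg$edges)) {
    w <- tg$weights %||% rep(1, nrow(tg$edges))
    A[tg$edges] <- w
    A[tg$edges[, 2:1, drop = FALSE]] <- w
  }
  dimnames(A) <- list(tg$labels, tg$labels)
  A
}

#' Threshold a connectivity matrix over a sparsity sweep
#'
#' One graph per grid point; because the edge ranking is computed once, the
#' edge sets are nested (the graph at a lower sparsity is a subgraph of the
#' graph at any higher sparsity).
#'
#' @inheritParams threshold_by_sparsity
#' @param lo,hi,step sparsity grid (defaults 0.06 to 0.40 by 0.01).
#' @return a list of [thresholded_graph()] objects, named by sparsity.
#' @export
sparsity_sweep <- function(cm, lo = 0.06, hi = 0.40, step = 0.01,
                           mode = c("binary", "weighted"),
                           rank = c("abs", "positive")) {
  mode <- match.arg(mode)
  rank <- match.arg(rank)
  if (lo > hi) stop("lo must not exceed hi")
  grid <- seq(lo, hi, by = step)
  out <- lapply(grid, function(S) threshold_by_sparsity(cm, S, mode, rank))
  names(out) <- sprintf("%.2f", grid)
  out
}
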