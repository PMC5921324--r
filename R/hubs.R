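# Hub identification from normalised betweenness centrality.

#' Normalise betweenness by the network mean
#'
#' bi = Bi / B, where B is the average betweenness over all nodes. If B = 0
#' (e.g. a complete graph) all bi are defined as 0 with a warning.
#'
#' @param Bi per-node betweenness values (nonnegative).
#' @return per-node normalised betweenness bi (mean 1 when B > 0).
#' @examples
#' normalize_betweenness(c(6, 0, 0, 0, 0))  # star graph: 5, 0, 0, 0, 0
#' @export
normalize_betweenness <- function(Bi) {
  if (length(Bi) < 1) stop("need at least one node")
  if (any(Bi < 0)) stop("negative betweenness values: upstream contract violation")
  B <- mean(Bi)
  if (B == 0) {
    warning("mean betweenness is 0; all normalised values set to 0")
    return(rep(0, length(Bi)))
  }
  Bi / B
}

#' Identify hub regions by normalised betweenness
#'
#' A region is a hub when its normalised betweenness exceeds `threshold`
#' (strictly; the conventional cutoff is 1.5 times the network average).
#'
#' @param bi per-node normalised betweenness.
#' @param labels region labels.
#' @param classes optional cortex class per region
#'   (`"primary"`, `"association"`, `"paralimbic"`); carried as metadata.
#' @param threshold hub cutoff on bi (default 1.5, strict `>`).
#' @return a `hub_table` data.frame with columns `region`, `class`, `bi`,
#'   `is_hub`, sorted by bi descending (ties by label).
#' @examples
#' identify_hubs(c(5, 0.5, 0.2), labels = c("A", "B", "C"))
#' @export
identify_hubs <- function(bi, labels = names(bi), classes = NULL,
                          threshold = 1.5) {
  if (is.null(labels)) labels <- default_regions(length(bi))
  if (length(labels) != length(bi))
    stop("labels do not align with the bi values")
  if (is.null(classes)) classes <- rep(NA_character_, length(bi))
  out <- data.frame(region = as.character(labels),
                    class = as.character(classes),
                    bi = as.numeric(bi),
                    is_hub = bi > threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$bi, out$region), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hub_table", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Hub table of a thresholded graph
#'
#' Convenience wrapper: betweenness -> normalisation -> hub flags.
#'
#' @param tg a [thresholded_graph()].
#' @param classes optional cortex class per region.
#' @param threshold hub cutoff on bi.
#' @return a `hub_table` (see [identify_hubs()]) with a `Bi` column added.
#' @export
hub_analysis <- function(tg, classes = NULL, threshold = 1.5) {
  bw <- betweenness_centrality(tg)
  bi <- normalize_betweenness(bw$node)
  tab <- identify_hubs(bi, labels = tg$labels, classes = classes,
                       threshold = threshold)
  tab$Bi <- bw$node[tab$region]
  tab
}

#' Export a network and its hubs for BrainNet Viewer
#'
#' Writes the `.node` file (x, y, z, colour code = hub flag, size = bi,
#' label) and the `.edge` file (N x N whitespace-delimited matrix) used by
#' BrainNet Viewer style renderers.
#'
#' @param hub_table a `hub_table` from [identify_hubs()] or [hub_analysis()].
#' @param coords data.frame with columns `region`, `x`, `y`, `z`.
#' @param matrix an N x N numeric matrix in region order (e.g. a thresholded
#'   adjacency), or NULL to skip the `.edge` file.
#' @param file_prefix output path prefix; writes `<prefix>.node` and
#'   `<prefix>.edge`.
#' @return invisibly, the paths written.
#' @export
write_brainnet <- function(hub_table, coords, matrix = NULL, file_prefix) {
  stopifnot(inherits(hub_table, "hub_table"))
  m <- match(hub_table$region, coords$region)
  if (anyNA(m))
    stop("coordinates missing for region(s): ",
         paste(hub_table$region[is.na(m)], collapse = ", "))
  node <- data.frame(
    x = coords$x[m], y = coords$y[m], z = coords$z[m],
    color = as.integer(hub_table$is_hub),
    size = hub_table$bi,
    label = gsub("[[:space:]]+", ".", hub_table$region)
  )
  node_path <- paste0(file_prefix, ".node")
  utils::write.table(node, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths <- node_path
  if (!is.null(matrix)) {
    edge_path <- paste0(file_prefix, ".edge")
    utils::write.table(format(matrix, trim = TRUE), edge_path, sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths <- c(paths, edge_path)
  }
  invisible(paths)
}
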