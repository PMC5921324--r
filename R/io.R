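# Plain-text readers/writers: regional metric tables and covariates as TSV,
# connectivity matrices as whitespace-delimited square text with a sidecar
# label file. All imaging preprocessing is upstream of this package, so no
# imaging formats are handled here.

#' Write / read a regional metric table as TSV
#'
#' Layout: header row, columns `subject_id`, `group`, then one column per
#' region label; one row per subject.
#'
#' @param table a [regional_metric_table()].
#' @param path output path.
#' @return `write_regional_table`: invisibly, the path.
#' @export
write_regional_table <- function(table, path) {
  stopifnot(inherits(table, "regional_metric_table"))
  df <- data.frame(subject_id = table$subject_ids, group = table$group,
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regional_table
#' @param metric metric name to record on the object read back.
#' @return `read_regional_table`: a [regional_metric_table()].
#' @export
read_regional_table <- function(path, metric = "metric") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  need <- c("subject_id", "group")
  if (!all(need %in% names(df)))
    stop("regional table must have subject_id and group columns")
  regions <- names(df)[!names(df) %in% need] # keep duplicates for the check below
  if (length(regions) < 1) stop("no region columns found")
  dup <- regions[duplicated(regions)]
  if (length(dup))
    stop("duplicated region column(s): ", paste(unique(dup), collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(regions))
  for (j in seq_along(regions)) {
    v <- suppressWarnings(as.numeric(df[[regions[j]]]))
    bad <- which(is.na(v) & !is.na(df[[regions[j]]]))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   bad[1], regions[j], df[[regions[j]]][bad[1]]))
    vals[, j] <- v
  }
  regional_metric_table(vals, subject_ids = df$subject_id, group = df$group,
                        regions = regions, metric = metric)
}

#' Write / read a connectivity matrix as square whitespace text
#'
#' The matrix is written as N rows of N whitespace-separated numbers with a
#' sidecar file of N region labels (one per line). On reading, asymmetry up
#' to 1e-8 is silently symmetrised; larger asymmetry is symmetrised by
#' averaging with a warning. The diagonal is zeroed.
#'
#' @param cm a [connectivity_matrix()].
#' @param path matrix path; the label sidecar defaults to `<path>.labels`.
#' @param labels_path optional sidecar path.
#' @return `write_matrix`: invisibly, the paths written.
#' @export
write_matrix <- function(cm, path, labels_path = paste0(path, ".labels")) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  utils::write.table(format(cm$values, trim = TRUE, digits = 10), path,
                     sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(cm$regions, labels_path)
  invisible(c(path, labels_path))
}

#' @rdname write_matrix
#' @param weight_kind,level recorded on the object read back; see
#'   [connectivity_matrix()].
#' @return `read_matrix`: a [connectivity_matrix()].
#' @export
read_matrix <- function(path, labels_path = paste0(path, ".labels"),
                        weight_kind = "correlation",
                        level = c("group", "subject")) {
  level <- match.arg(level)
  M <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(M) <- NULL
  if (nrow(M) != ncol(M))
    stop(sprintf("matrix is not square: %d x %d", nrow(M), ncol(M)))
  labels <- if (file.exists(labels_path)) readLines(labels_path)
  else default_regions(ncol(M))
  if (length(labels) != ncol(M))
    stop("label sidecar length does not match the matrix")
  asym <- max(abs(M - t(M)))
  if (asym > 1e-8)
    warning(sprintf("matrix asymmetry %.3g; symmetrised by averaging", asym))
  M <- symmetrize0(M)
  connectivity_matrix(M, labels, weight_kind = weight_kind, level = level)
}

#' Write / read a covariates table as TSV
#'
#' @param covariates data.frame with `subject_id`, `group`, `age`, `sex`,
#'   `MMSE`, `MoCA`.
#' @param path file path.
#' @return the path (write) or the data.frame (read).
#' @export
write_covariates <- function(covariates, path) {
  utils::write.table(covariates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Synthetic region metadata for an N-region parcellation
#'
#' Generates a metadata table (label, abbreviation, synthetic ring-layout
#' coordinates in mm, cortex class cycling through primary / association /
#' paralimbic). The coordinates and classes are synthetic placeholders for
#' rendering and hub bookkeeping, not anatomical claims; real analyses
#' should supply their own metadata TSV with columns `region`, `abbrev`,
#' `x`, `y`, `z`, `class`.
#'
#' @param n number of regions.
#' @return a data.frame with one row per region.
#' @export
synthetic_region_metadata <- function(n = 90) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(
    region = default_regions(n),
    abbrev = default_regions(n),
    x = round(70 * cos(theta), 1),
    y = round(70 * sin(theta), 1),
    z = round(20 * sin(2 * theta), 1),
    class = rep(c("primary", "association", "paralimbic"), length.out = n),
    stringsAsFactors = FALSE
  )
}

#' @rdname synthetic_region_metadata
#' @param path TSV path with columns `region`, `abbrev`, `x`, `y`, `z`,
#'   `class`.
#' @export
read_region_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("region", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("region metadata missing column(s): ", paste(miss, collapse = ", "))
  df
}
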