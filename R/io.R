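#' Write a numeric matrix as delimited text
#'
#' Tab-separated, '.' decimal, no header or row names -- the package's
#' on-disk matrix format. Full double precision is retained so write/read
#' round-trips are bitwise exact.
#'
#' @param x Numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(is.matrix(x), is.numeric(x))
  lines <- apply(x, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a delimited numeric matrix
#'
#' Parses a tab/whitespace-separated numeric matrix, validating that rows
#' are rectangular and every cell is numeric. For `what = "bold"` the
#' matrix is wrapped as a [bold_matrix()] (transposed first if
#' `orientation = "frames_by_nodes"`); for `what = "correlation"` it is
#' checked for symmetry and unit diagonal (tolerance 1e-6) and returned as
#' a [build_correlation()] model.
#'
#' @param path Input file path.
#' @param what `"matrix"`, `"bold"` or `"correlation"`.
#' @param orientation `"nodes_by_frames"` (default) or `"frames_by_nodes"`
#'   (bold only).
#' @return A matrix, `bold_matrix`, or `correlation_model`.
#' @export
read_matrix <- function(path, what = c("matrix", "bold", "correlation"),
                        orientation = c("nodes_by_frames",
                                        "frames_by_nodes")) {
  what <- match.arg(what)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_invalid("empty matrix file: ", path)
  rows <- strsplit(lines, "[\t ]+")
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L)
    stop_invalid("ragged rows in ", path, ": row ",
                 which(widths != widths[1L])[1L], " has ",
                 widths[widths != widths[1L]][1L], " fields, expected ",
                 widths[1L])
  x <- suppressWarnings(
    matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop_invalid("non-numeric cell at row ", bad["row"], ", column ",
                 bad["col"], " in ", path)
  }
  switch(what,
    matrix = x,
    bold = {
      if (orientation == "frames_by_nodes") x <- t(x)
      bold_matrix(x)
    },
    correlation = {
      if (nrow(x) != ncol(x) || max(abs(x - t(x))) > 1e-6)
        stop_invalid("correlation input is not symmetric: ", path)
      if (max(abs(diag(x) - 1)) > 1e-6)
        stop_invalid("correlation input lacks unit diagonal: ", path)
      build_correlation((x + t(x)) / 2)
    })
}

#' Write a surrogate BOLD matrix with its sidecar config
#'
#' Writes the nodes x frames values as delimited text and a YAML sidecar
#' (`<path>.yaml`) recording the full surrogate spec -- correlation kind
#' and parameters, frame count, temporal model, and seed -- so any draw is
#' reproducible from its files alone.
#'
#' @param spec A [surrogate_spec()].
#' @param path Output path for the matrix.
#' @param bold Optional pre-drawn [sample_bold()] result for this spec.
#' @return `path`, invisibly.
#' @export
write_surrogate <- function(spec, path, bold = NULL) {
  stopifnot(inherits(spec, "surrogate_spec"))
  if (is.null(bold)) bold <- sample_bold(spec)
  write_matrix(bold$values, path)
  cs <- spec$correlation$spec
  config <- list(
    n_nodes = cs$n_nodes,
    correlation = list(kind = cs$kind,
                       module_sizes = cs$module_sizes,
                       rho_within = cs$rho_within,
                       rho_between = cs$rho_between,
                       n_factors = cs$n_factors,
                       seed = cs$seed),
    n_frames = spec$n_frames,
    temporal_model = spec$temporal_model,
    ar_coefficient = spec$ar_coefficient,
    seed = spec$seed,
    orientation = "nodes_by_frames")
  yaml::write_yaml(config, paste0(path, ".yaml"))
  invisible(path)
}

#' Rebuild a surrogate spec from a sidecar config
#'
#' @param path Path to the matrix file written by [write_surrogate()] (the
#'   sidecar is `<path>.yaml`).
#' @return The reconstructed [surrogate_spec()].
#' @export
read_surrogate_spec <- function(path) {
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar)) stop_invalid("sidecar not found: ", sidecar)
  cfg <- yaml::read_yaml(sidecar)
  cs <- cfg$correlation
  spec <- correlation_spec(cfg$n_nodes, cs$kind,
                           module_sizes = cs$module_sizes,
                           rho_within = cs$rho_within,
                           rho_between = cs$rho_between %||% 0,
                           n_factors = cs$n_factors,
                           seed = cs$seed)
  surrogate_spec(spec, cfg$n_frames, cfg$temporal_model,
                 cfg$ar_coefficient %||% 0, cfg$seed)
}

#' Write edge labels as a node-by-node label matrix and edge list
#'
#' The label matrix has -1 on the diagonal (self-edges are undefined); the
#' edge list has 1-based columns `i`, `j`, `label`.
#'
#' @param labels A `community_labels` with its edge set.
#' @param matrix_path,edgelist_path Output paths (either may be NULL).
#' @param n_nodes Node count when the labels carry no edge set.
#' @return Invisibly, NULL.
#' @export
write_labels <- function(labels, matrix_path = NULL, edgelist_path = NULL,
                         n_nodes = NULL) {
  stopifnot(inherits(labels, "community_labels"))
  es <- labels$edge_set %||% edge_set(n_nodes)
  n <- max(es$j)
  if (!is.null(matrix_path)) {
    m <- matrix(-1L, n, n)
    m[cbind(es$i, es$j)] <- labels$labels
    m[cbind(es$j, es$i)] <- labels$labels
    write_matrix(m + 0, matrix_path)
  }
  if (!is.null(edgelist_path)) {
    df <- data.frame(i = es$i, j = es$j, label = labels$labels)
    utils::write.table(df, edgelist_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}
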