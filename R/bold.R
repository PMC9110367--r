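#' Construct a BOLD matrix
#'
#' Wraps an N x T (nodes x frames) numeric matrix. Rows are regional time
#' series; columns are frames. Use [zscore_bold()] to attach the z-scored
#' form required by the edge-centric operations.
#'
#' @param values Numeric N x T matrix with N >= 2 and T >= 2.
#' @param node_ids Optional character vector of N node labels.
#' @return An object of class `bold_matrix` with elements `values`,
#'   `node_ids`, and (after z-scoring) `z_values`, `mu`, `sigma`.
#' @export
bold_matrix <- function(values, node_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_invalid("values must be a numeric matrix")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop_invalid("need at least 2 nodes and 2 frames, got ",
                 nrow(values), " x ", ncol(values))
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(values)))
  stopifnot(length(node_ids) == nrow(values))
  structure(list(values = values, node_ids = node_ids,
                 z_values = NULL, mu = NULL, sigma = NULL),
            class = "bold_matrix")
}

#' Z-score a BOLD matrix row-wise
#'
#' Centres each regional time series and divides by its population standard
#' deviation (denominator T). Under this convention the node correlation
#' estimator is `r_ij = sum_t z_i(t) z_j(t) / (T - 1)` and every
#' edge-centric identity in the package is exact. The original per-node mean
#' and standard deviation are retained for provenance.
#'
#' @param bold A [bold_matrix()] (or plain numeric matrix).
#' @return The same `bold_matrix` with `z_values`, `mu`, `sigma` filled in.
#' @examples
#' b <- zscore_bold(matrix(rnorm(40), 4, 10))
#' rowMeans(b$z_values)  # ~0
#' @export
zscore_bold <- function(bold) {
  if (is.matrix(bold)) bold <- bold_matrix(bold)
  stopifnot(inherits(bold, "bold_matrix"))
  x <- bold$values
  t_len <- ncol(x)
  mu <- rowMeans(x)
  centred <- x - mu
  sigma <- sqrt(rowSums(centred^2) / t_len)
  if (any(sigma == 0)) {
    bad <- bold$node_ids[which(sigma == 0)]
    stop_invalid("constant (zero-variance) signal for node(s): ",
                 paste(bad, collapse = ", "))
  }
  bold$z_values <- centred / sigma
  bold$mu <- mu
  bold$sigma <- sigma
  bold
}

# Extract the z-scored matrix, z-scoring on the fly when needed. A plain
# matrix is trusted as already z-scored (used for exact-null frames that are
# standard Gaussian by construction).
z_matrix <- function(bold) {
  if (is.matrix(bold)) return(bold)
  stopifnot(inherits(bold, "bold_matrix"))
  if (is.null(bold$z_values)) bold <- zscore_bold(bold)
  bold$z_values
}

#' Empirical node functional connectivity
#'
#' The N x N Pearson correlation matrix of the regional time series -- the
#' nFC. Computed with [stats::cor()] on the raw rows, so the diagonal is
#' exactly one regardless of the z-scoring denominator convention.
#'
#' @param bold A [bold_matrix()] or plain N x T matrix.
#' @return An N x N correlation matrix.
#' @export
empirical_nfc <- function(bold) {
  x <- if (is.matrix(bold)) bold else bold$values
  stats::cor(t(x))
}
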