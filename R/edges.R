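#' Enumerate the edge set of N nodes
#'
#' The E = N(N-1)/2 unordered node pairs (i, j), i < j, in lexicographic
#' order. This fixed order indexes the rows of every edge-level matrix in
#' the package, so outputs are bit-reproducible.
#'
#' @param n_nodes Number of nodes N (>= 2).
#' @return A data frame of class `edge_set` with integer columns `i`, `j`
#'   and one row per edge.
#' @examples
#' nrow(edge_set(200))  # 19900
#' @export
edge_set <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L)
    stop_invalid("need at least 2 nodes")
  idx <- which(upper.tri(diag(n_nodes)), arr.ind = TRUE)
  es <- data.frame(i = idx[, "row"], j = idx[, "col"])
  es <- es[order(es$i, es$j), , drop = FALSE]
  rownames(es) <- NULL
  class(es) <- c("edge_set", "data.frame")
  es
}

#' Look up edge indices for node pairs
#'
#' @param es An [edge_set()].
#' @param i,j Node indices (vectorised); order within a pair is ignored.
#' @return Integer positions of the edges in `es`.
#' @export
edge_index <- function(es, i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo == hi)) stop_invalid("self-pairs (i == j) are not edges")
  n <- max(es$j)
  if (any(lo < 1L) || any(hi > n)) stop_invalid("node index out of range")
  # lexicographic rank of (lo, hi) among pairs with i < j
  as.integer((lo - 1L) * n - lo * (lo - 1L) / 2 + (hi - lo))
}

#' Edge time series
#'
#' The per-edge cofluctuation series `c_ij(t) = z_i(t) z_j(t)`: the
#' element-wise product of the two z-scored regional signals. Its time
#' average (with denominator T - 1) is exactly the node correlation r_ij
#' under the package's z-scoring convention.
#'
#' @param bold A z-scored [bold_matrix()] or plain z-scored matrix.
#' @return An object of class `edge_ts`: list with `values` (E x T matrix
#'   in [edge_set()] order) and `edge_set`.
#' @export
edge_time_series <- function(bold) {
  z <- z_matrix(bold)
  es <- edge_set(nrow(z))
  values <- z[es$i, , drop = FALSE] * z[es$j, , drop = FALSE]
  rownames(values) <- paste0(es$i, "-", es$j)
  structure(list(values = values, edge_set = es), class = "edge_ts")
}

#' Empirical edge functional connectivity
#'
#' The E x E matrix of normalised inner products between all pairs of edge
#' time series: entry (e, f) is `sum_t c_e(t) c_f(t)` divided by the norms
#' of the two rows, so the matrix is symmetric with unit diagonal and
#' entries in `[-1, 1]`.
#'
#' @param ets An [edge_time_series()] (or a z-scored [bold_matrix()], which
#'   is converted first).
#' @return An object of class `edge_fc_matrix`: list with `values` (E x E),
#'   `edge_set`, and `provenance = "empirical"`.
#' @export
edge_fc <- function(ets) {
  if (!inherits(ets, "edge_ts")) ets <- edge_time_series(ets)
  v <- ets$values
  if (ncol(v) < 2L) stop_invalid("need at least 2 frames")
  norms <- sqrt(rowSums(v^2))
  if (any(norms == 0)) {
    bad <- rownames(v)[norms == 0]
    stop_invalid("all-zero edge time series for edge(s): ",
                 paste(utils::head(bad, 5L), collapse = ", "))
  }
  g <- tcrossprod(v / norms)
  g[g > 1] <- 1; g[g < -1] <- -1
  diag(g) <- 1
  structure(list(values = g, edge_set = ets$edge_set,
                 provenance = "empirical"),
            class = "edge_fc_matrix")
}

#' Binarise edge time series by cofluctuation sign
#'
#' Entry 1 where the cofluctuation is positive (the two z-scored signals
#' agree in sign), 0 where negative. Exact zeros binarise to 0 and are
#' counted in `tie_count`; they have probability zero under the null, so a
#' nonzero count flags degenerate input. Under the static Gaussian null the
#' time average of row (i, j) converges to the arcsine probability
#' `1/2 + asin(r_ij) / pi` (see [bernoulli_probability()]).
#'
#' @param ets An [edge_time_series()].
#' @return An object of class `binary_edge_matrix`: list with `values`
#'   (E x T, 0/1), `edge_set`, `tie_count`.
#' @export
binarize_edges <- function(ets) {
  if (!inherits(ets, "edge_ts")) ets <- edge_time_series(ets)
  b <- (ets$values > 0) * 1L
  structure(list(values = b, edge_set = ets$edge_set,
                 tie_count = sum(ets$values == 0)),
            class = "binary_edge_matrix")
}
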