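#' Analytic edge FC predicted from the node FC
#'
#' Under a zero-joint-cumulant (e.g. Gaussian) ergodic model, the expected
#' product of two edge time series reduces by Isserlis' theorem to a sum of
#' pairwise nFC products, giving the closed form
#' \deqn{eFC_{jk,lm} = \frac{r_{jk} r_{lm} + r_{jl} r_{km} + r_{jm} r_{kl}}
#'   {\sqrt{1 + 2 r_{jk}^2}\,\sqrt{1 + 2 r_{lm}^2}}.}
#' The diagonal is identically 1 and the empirical [edge_fc()] converges to
#' this prediction elementwise as T grows.
#'
#' @param r A [build_correlation()] model or plain correlation matrix.
#' @return An `edge_fc_matrix` with `provenance = "predicted"`.
#' @export
predict_efc <- function(r) {
  R <- if (inherits(r, "correlation_model")) r$R else r
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  es <- edge_set(nrow(R))
  rv <- R[cbind(es$i, es$j)]
  num <- outer(rv, rv) +
    R[es$i, es$i] * R[es$j, es$j] + R[es$i, es$j] * R[es$j, es$i]
  den <- sqrt(1 + 2 * rv^2)
  g <- num / outer(den, den)
  g <- (g + t(g)) / 2
  diag(g) <- 1
  rownames(g) <- colnames(g) <- paste0(es$i, "-", es$j)
  structure(list(values = g, edge_set = es, provenance = "predicted"),
            class = "edge_fc_matrix")
}

#' Predicted distance between two edges
#'
#' The l1 distance between two rows of the unnormalised eFC, expressed in
#' nFC terms: `sum_{l,m} 3 |r_jl r_mk - r_j'l r_mk'|` for edges (j, k) and
#' (j', k'). Distances are computed in correlation units (inner-product
#' scale factors divided out), so they are independent of T; only relative
#' distances matter for clustering. Symmetric in its edge arguments and
#' zero for identical edges.
#'
#' @param r A correlation model or matrix.
#' @param edge_a,edge_b Length-2 integer vectors (node pairs).
#' @return A nonnegative scalar.
#' @export
edge_distance <- function(r, edge_a, edge_b) {
  R <- if (inherits(r, "correlation_model")) r$R else r
  n <- nrow(R)
  check_edge <- function(e, name) {
    e <- as.integer(e)
    if (length(e) != 2L || any(e < 1L) || any(e > n) || e[1L] == e[2L])
      stop_invalid(name, " is not a valid edge for ", n, " nodes")
    e
  }
  a <- check_edge(edge_a, "edge_a")
  b <- check_edge(edge_b, "edge_b")
  3 * sum(abs(outer(R[a[1L], ], R[a[2L], ]) -
              outer(R[b[1L], ], R[b[2L], ])))
}

#' Predicted node distance from the nFC
#'
#' Summing predicted edge distances over shared targets bounds the distance
#' between two nodes' edge profiles by `c * (1 - r_ij)^(1/2)` with c
#' independent of the pair, so `d_ij = (1 - r_ij)^(1/2)` predicts (up to
#' scale) the edge-cluster dissimilarity of nodes i and j without ever
#' forming the eFC. A monotone decreasing transform of r_ij with range
#' `[0, sqrt(2)]`.
#'
#' @param r A correlation model or matrix with entries in `[-1, 1]`.
#' @return An N x N symmetric matrix of class `node_distance_matrix` (zero
#'   diagonal).
#' @export
predicted_node_distance <- function(r) {
  R <- if (inherits(r, "correlation_model")) r$R else r
  if (max(abs(R)) > 1 + 1e-12)
    stop_invalid("correlation entries must lie in [-1, 1]")
  d <- sqrt(pmax(1 - R, 0))
  diag(d) <- 0
  structure(d, class = c("node_distance_matrix", class(d)))
}

#' Sign-concordance probability of a correlated Gaussian pair
#'
#' The probability that two zero-mean unit-variance jointly Gaussian
#' signals with correlation r agree in sign at a given frame:
#' `p = 1/2 + asin(r) / pi` (the arcsine / orthant law). This is the
#' success probability of the Bernoulli model for binarised edge time
#' series: p(0) = 1/2, p(1) = 1, p(-r) = 1 - p(r), and p is close to
#' `1/2 + r / pi` for small r.
#'
#' @param r Correlation(s) in `[-1, 1]` (vectorised).
#' @return Probabilities in `[0, 1]`.
#' @examples
#' bernoulli_probability(c(-1, 0, 1))  # 0, 0.5, 1
#' @export
bernoulli_probability <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12))
    stop_invalid("correlations must lie in [-1, 1]")
  out <- 0.5 + asin(pmin(1, pmax(-1, r))) / pi
  attributes(out) <- attributes(r)   # keep matrix shape
  out
}

#' Predicted time-average of binarised edge series
#'
#' Applies [bernoulli_probability()] elementwise to the nFC: the (i, j)
#' entry predicts the time average of the binarised edge series of the pair
#' under the static null. Averaged binary edges therefore reconstruct a
#' monotone (near-linear for small r) transform of the nFC.
#'
#' @param r A correlation model or matrix.
#' @return An N x N matrix of probabilities (diagonal 1).
#' @export
predict_binary_nfc <- function(r) {
  R <- if (inherits(r, "correlation_model")) r$R else r
  p <- bernoulli_probability(R)
  diag(p) <- 1
  p
}

#' Expected frame conditional on a seed node's activity
#'
#' For jointly Gaussian frames, the conditional expectation of the whole
#' frame given that seed node k has z-value `seed_value` is
#' `seed_value * R[, k]` -- the seed column of the nFC scaled by the seed
#' activity. This is the foundational coactivation-pattern (CAP) property:
#' frames selected for high seed activity look like the seed's FC map, with
#' alignment proportional to the activity level.
#'
#' @param r A correlation model or matrix.
#' @param seed_node Node index k.
#' @param seed_value Conditioning z-value.
#' @return An N-vector.
#' @export
caps_expected_frame <- function(r, seed_node, seed_value) {
  R <- if (inherits(r, "correlation_model")) r$R else r
  seed_node <- as.integer(seed_node)
  if (length(seed_node) != 1L || is.na(seed_node) ||
      seed_node < 1L || seed_node > nrow(R))
    stop_invalid("seed_node out of range")
  seed_value * R[, seed_node]
}

#' Seed-sorted similarity curves (CAP percentile sweep)
#'
#' Sorts frames in descending order of the seed node's activity (ties
#' broken by frame index) and reports, per percentile bin:
#'
#' * `frame_similarity` -- the mean over the bin of the Pearson correlation
#'   between each single frame and the seed column of the nFC;
#' * `cumulative_similarity` -- the correlation between the running average
#'   of all frames down to that percentile and the seed column.
#'
#' On null surrogates the per-frame similarity decreases with the seed
#' percentile, and the cumulative curve rises quickly, plateaus while
#' weakly-correlated middle frames accumulate, then drops sharply once the
#' anticorrelated tail enters the average.
#'
#' @param bold A z-scored [bold_matrix()] or plain z-scored matrix.
#' @param r A correlation model or matrix.
#' @param seed_node Seed node index.
#' @param n_bins Number of percentile bins (<= T).
#' @return A data frame with columns `percentile` (upper edge of each bin,
#'   100 = top frames), `frame_similarity`, `cumulative_similarity`.
#' @export
caps_similarity_curves <- function(bold, r, seed_node, n_bins = 100L) {
  z <- z_matrix(bold)
  R <- if (inherits(r, "correlation_model")) r$R else r
  seed_node <- as.integer(seed_node)
  if (seed_node < 1L || seed_node > nrow(z))
    stop_invalid("seed_node out of range")
  t_len <- ncol(z)
  n_bins <- min(as.integer(n_bins), t_len)
  if (stats::sd(z[seed_node, ]) == 0)
    stop_invalid("seed node has constant signal")
  ref <- R[, seed_node]
  ord <- order(-z[seed_node, ], seq_len(t_len))
  zs <- z[, ord, drop = FALSE]
  frame_sim <- as.numeric(stats::cor(zs, ref))
  cum_mean <- t(apply(zs, 1L, cumsum)) / rep(seq_len(t_len),
                                             each = nrow(z))
  cum_sim <- as.numeric(stats::cor(cum_mean, ref))
  # bin frame ranks into percentile bins (bin 1 = highest seed activity)
  bin <- ceiling(seq_len(t_len) / t_len * n_bins)
  bin_edges <- 100 * (1 - (seq_len(n_bins) - 0.5) / n_bins)
  last_in_bin <- vapply(seq_len(n_bins), function(b) max(which(bin == b)),
                        integer(1))
  data.frame(percentile = bin_edges,
             frame_similarity = as.numeric(
               tapply(frame_sim, bin, mean)),
             cumulative_similarity = cum_sim[last_in_bin])
}
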