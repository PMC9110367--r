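#' Root-sum-of-squares cofluctuation amplitude
#'
#' The per-frame amplitude of the edge time series vector. Two conventions:
#'
#' * `"upper_triangular"` (default, the published measure):
#'   `RSS(t) = sqrt(sum_{i<j} c_ij(t)^2)`.
#' * `"all_pairs"`: all N^2 ordered pairs are included, which collapses
#'   exactly to the squared Euclidean norm of the z-scored frame,
#'   `RSS_all(t) = ||z(t)||^2`.
#'
#' The two agree up to a factor `sqrt(2)` and a fourth-moment correction
#' that vanishes as N grows; [kurtosis_ratio()] monitors that correction.
#' Both are computed from node sums (`||z||^2` and `sum z^4`) without
#' materialising the E x T edge matrix.
#'
#' @param bold A z-scored [bold_matrix()] or plain z-scored matrix.
#' @param convention `"upper_triangular"` or `"all_pairs"`.
#' @return An object of class `rss_series`: numeric length-T vector with
#'   attribute `convention`.
#' @examples
#' z <- matrix(rnorm(30), 3, 10)
#' all.equal(as.numeric(rss(z, "all_pairs")), colSums(z^2))
#' @export
rss <- function(bold, convention = c("upper_triangular", "all_pairs")) {
  convention <- match.arg(convention)
  z <- z_matrix(bold)
  s2 <- colSums(z^2)
  out <- if (convention == "all_pairs") {
    s2
  } else {
    s4 <- colSums(z^4)
    sqrt(pmax(s2^2 - s4, 0) / 2)
  }
  structure(out, convention = convention, class = "rss_series")
}

#' Fourth-moment diagnostic for the RSS norm approximation
#'
#' The upper-triangular RSS approximates `||z(t)||^2 / sqrt(2)` up to the
#' relative size of the summed fourth moments:
#' `(sum_i mean_t z_i^4) / (mean_t ||z(t)||^4)`. For Gaussian signals this
#' ratio is bounded by `3 N / N^2 = 3 / N` in expectation, so the
#' approximation (and the Gamma-mixture null built on it) improves with the
#' number of nodes. A value near 1 (e.g. very small N) flags that the
#' approximation is invalid.
#'
#' @param bold A z-scored [bold_matrix()] or plain z-scored matrix.
#' @return A scalar in `[0, 1]`.
#' @export
kurtosis_ratio <- function(bold) {
  z <- z_matrix(bold)
  num <- sum(rowMeans(z^4))
  den <- mean(colSums(z^2)^2)
  num / den
}

#' FC reconstruction from RSS-ranked frames
#'
#' Sorts frames by RSS and measures how well the top (or bottom) fraction
#' reconstructs the nFC: the selected frames' outer products `z(t) z(t)'`
#' are averaged and compared with the model nFC by Pearson correlation of
#' the upper triangles. High-RSS frames reconstructing the nFC much better
#' than low-RSS frames is the hallmark edge-centric finding, and it is
#' reproduced by the static null model.
#'
#' @param bold A z-scored [bold_matrix()] or plain z-scored matrix.
#' @param r A [build_correlation()] model or plain correlation matrix (the
#'   reference nFC).
#' @param fractions Numeric vector of frame fractions in `(0, 1]`.
#' @param convention RSS convention used for ranking.
#' @return A data frame with columns `fraction`, `direction`
#'   (`"descending"` / `"ascending"`), `n_frames`, `similarity`.
#' @export
frame_sorted_reconstruction <- function(bold, r, fractions = c(0.05, 1),
                                        convention = "upper_triangular") {
  z <- z_matrix(bold)
  R <- if (inherits(r, "correlation_model")) r$R else r
  stopifnot(is.matrix(R), all(dim(R) == nrow(z)))
  if (any(fractions <= 0) || any(fractions > 1))
    stop_invalid("fractions must lie in (0, 1]")
  t_len <- ncol(z)
  amp <- as.numeric(rss(z, convention))
  # ties broken by frame index for determinism
  ord_desc <- order(-amp, seq_len(t_len))
  ord_asc <- order(amp, seq_len(t_len))
  rows <- lapply(fractions, function(f) {
    n_sel <- floor(f * t_len)
    if (n_sel < 1L)
      stop_invalid("fraction ", f, " selects zero frames out of ", t_len)
    do.call(rbind, lapply(c("descending", "ascending"), function(dir) {
      sel <- if (dir == "descending") ord_desc[seq_len(n_sel)]
             else ord_asc[seq_len(n_sel)]
      fc <- tcrossprod(z[, sel, drop = FALSE]) / n_sel
      data.frame(fraction = f, direction = dir, n_frames = n_sel,
                 similarity = fc_similarity(fc, R))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
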