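#' Whiten a BOLD matrix against a correlation model
#'
#' Computes `W = R^(-1/2) Z` using the spectral pseudo-inverse square root
#' (eigenvalues below 1e-10 are treated as a null space). On null
#' surrogates the whitened sample covariance converges to the identity, and
#' un-whitening with `R^(1/2)` round-trips exactly because both square
#' roots come from the same eigensystem. If the correlation model is rank
#' deficient and the data carry energy in the dropped directions, that
#' energy cannot be represented after whitening; a warning is issued and
#' the data are projected onto the retained eigenspace.
#'
#' @param bold A z-scored [bold_matrix()] or plain z-scored matrix.
#' @param r A [build_correlation()] model or correlation matrix.
#' @return An N x T matrix of whitened frames.
#' @export
whiten_bold <- function(bold, r) {
  z <- z_matrix(bold)
  model <- as_correlation_model(r)
  stopifnot(nrow(z) == length(model$node_ids))
  dropped <- model$values <= 1e-10
  if (any(dropped)) {
    null_basis <- model$vectors[, dropped, drop = FALSE]
    energy <- sum(crossprod(null_basis, z)^2)
    if (energy > 1e-8 * sum(z^2))
      warning("data carry energy in the null space of R; ",
              "projecting onto the retained eigenspace")
  }
  correlation_isqrt(model) %*% z
}

#' Per-frame eigenvector alignment profile
#'
#' Decomposes each frame's RSS over the nFC eigensystem. Writing
#' `w(t) = R^(-1/2) z(t)` and `cos^2 theta_i(t)` for the squared cosine
#' between w(t) and eigenvector u_i, the all-pairs RSS recomposes exactly
#' as \deqn{RSS_{all}(t)/\sqrt2 = \frac{1}{\sqrt2} \sum_i \lambda_i
#' \cos^2\theta_i(t)\, \lVert w(t)\rVert^2,} with `sum_i cos^2 theta_i = 1`
#' per frame and the bound `RSS_all/sqrt(2) <= lambda_max ||w||^2 /
#' sqrt(2)`, attained exactly when the frame aligns with the leading
#' eigenvector. High-RSS frames are therefore frames whose whitened energy
#' loads on the top eigenvalues.
#'
#' @param bold A z-scored [bold_matrix()] or plain z-scored matrix.
#' @param r A correlation model or matrix.
#' @return An object of class `alignment_profile`: list with `w_norm2`
#'   (per-frame `||w||^2`), `cos2` (T x N matrix of squared cosines),
#'   `rss_recomposed` (per-frame eigen-recomposition of RSS_all/sqrt(2)),
#'   `rss_all` (directly computed `||z||^2 / sqrt(2)`), `pc1` (per-frame
#'   leading-eigenvector coefficient `<u1, z(t)>`), `zero_frames` (indices
#'   of zero frames whose cosines are undefined, NA in `cos2`), and
#'   `degenerate` (TRUE when eigenvalue gaps < 1e-10 make individual
#'   eigenvectors non-unique).
#' @export
alignment_profile <- function(bold, r) {
  z <- z_matrix(bold)
  model <- as_correlation_model(r)
  w <- whiten_bold(z, model)
  w_norm2 <- colSums(w^2)
  coef <- crossprod(model$vectors, w)            # <u_i, w(t)>, N x T
  cos2 <- t(coef^2) / ifelse(w_norm2 > 0, w_norm2, NA_real_)
  zero_frames <- which(w_norm2 == 0)
  rss_recomposed <- colSums(model$values * coef^2) / sqrt(2)
  structure(list(w_norm2 = w_norm2, cos2 = cos2,
                 rss_recomposed = rss_recomposed,
                 rss_all = colSums(z^2) / sqrt(2),
                 pc1 = as.numeric(crossprod(model$vectors[, 1L], z)),
                 zero_frames = zero_frames,
                 degenerate = any(diff(model$values) > -1e-10)),
            class = "alignment_profile")
}

#' Rank-1 nFC approximation from the leading eigenvector
#'
#' `lambda_1 u_1 u_1'` -- the FC pattern expressed by a frame perfectly
#' aligned with the leading eigenvector. Sign-invariant in u_1. When the
#' top eigenvalue is degenerate (gap below 1e-10, e.g. the identity), the
#' returned leading direction is the deterministic tie-broken one and the
#' result carries attribute `degenerate = TRUE`.
#'
#' @param r A correlation model or matrix.
#' @return An N x N rank-1 matrix with attribute `degenerate`.
#' @export
rank1_fc <- function(r) {
  model <- as_correlation_model(r)
  if (model$values[1L] <= 0) stop_invalid("leading eigenvalue must be > 0")
  u1 <- model$vectors[, 1L]
  out <- model$values[1L] * tcrossprod(u1)
  attr(out, "degenerate") <-
    length(model$values) > 1L &&
    (model$values[1L] - model$values[2L]) < 1e-10
  out
}

#' Per-frame similarity to leading-eigenvector FC estimates
#'
#' For each frame, the Pearson correlation (upper triangles) between its
#' instantaneous FC estimate `z(t) z(t)'` and each rank-1 eigenvector
#' estimate `lambda_i u_i u_i'` for the k leading eigenvectors. Because the
#' similarity is a correlation it is scale-invariant, so weighting by
#' lambda_i or not gives identical values. Also returns the per-frame RSS
#' and leading-eigenvector coefficient: across null frames, large |PC1|
#' coefficients go with large RSS.
#'
#' @param bold A z-scored [bold_matrix()] or plain z-scored matrix.
#' @param r A correlation model or matrix.
#' @param k Number of leading eigenvectors (<= N).
#' @return A data frame with columns `frame`, `rss`, `pc1`, and
#'   `sim_u1 ... sim_uk`.
#' @export
top_eigvec_similarity <- function(bold, r, k = 4L) {
  z <- z_matrix(bold)
  model <- as_correlation_model(r)
  n <- nrow(z)
  k <- as.integer(k)
  if (k < 1L || k > n) stop_invalid("k must lie in [1, N]")
  # upper triangle of z z' for every frame, as an E x T matrix
  es <- edge_set(n)
  frame_fc <- z[es$i, , drop = FALSE] * z[es$j, , drop = FALSE]
  sims <- vapply(seq_len(k), function(i) {
    ref_mat <- model$values[i] * tcrossprod(model$vectors[, i])
    ref <- ref_mat[cbind(es$i, es$j)]
    as.numeric(stats::cor(frame_fc, ref))
  }, numeric(ncol(z)))
  out <- data.frame(frame = seq_len(ncol(z)),
                    rss = as.numeric(rss(z)),
                    pc1 = as.numeric(crossprod(model$vectors[, 1L], z)))
  sims <- as.data.frame(sims)
  names(sims) <- paste0("sim_u", seq_len(k))
  cbind(out, sims)
}
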