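#' Specify a surrogate BOLD simulation
#'
#' A `surrogate_spec` pairs a correlation model with the temporal model of
#' the frames. Under the static null model (`temporal_model = "iid"`) each
#' frame is an independent draw from `N(0, R)`; the `"ar1"` contrast keeps
#' the same stationary spatial covariance `R` but makes frames a first-order
#' autoregressive process, isolating temporal structure as the only
#' departure from the null.
#'
#' @param correlation A [correlation_spec()] or [build_correlation()] model.
#' @param n_frames Number of frames T (>= 2).
#' @param temporal_model `"iid"` (the null) or `"ar1"`.
#' @param ar_coefficient Lag-1 autoregression coefficient in `(-1, 1)`.
#' @param seed Integer RNG seed; every draw from this spec is reproducible.
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(correlation, n_frames,
                           temporal_model = c("iid", "ar1"),
                           ar_coefficient = 0, seed = 1L) {
  temporal_model <- match.arg(temporal_model)
  if (inherits(correlation, "correlation_spec"))
    correlation <- build_correlation(correlation)
  if (is.matrix(correlation)) correlation <- build_correlation(correlation)
  stopifnot(inherits(correlation, "correlation_model"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L)
    stop_invalid("n_frames must be at least 2")
  if (temporal_model == "ar1" && abs(ar_coefficient) >= 1)
    stop_invalid("ar_coefficient must lie in (-1, 1)")
  structure(list(correlation = correlation, n_frames = n_frames,
                 temporal_model = temporal_model,
                 ar_coefficient = ar_coefficient, seed = as.integer(seed)),
            class = "surrogate_spec")
}

#' Sample a surrogate BOLD matrix
#'
#' Draws an N x T BOLD matrix from the spec's correlation model. Frames are
#' coloured with the symmetric square root `R^(1/2) = U Lambda^(1/2) U'`
#' (not a Cholesky factor), so whitening with the spectral inverse square
#' root round-trips exactly. For `"ar1"`, innovations are scaled by
#' `sqrt(1 - a^2)` so the stationary covariance equals `R`; the chain is
#' started from its stationary law.
#'
#' @param spec A [surrogate_spec()].
#' @return A [bold_matrix()] with the raw (not yet z-scored) values.
#' @examples
#' sp <- surrogate_spec(correlation_spec(4, "identity"), n_frames = 100,
#'                      seed = 7)
#' b <- sample_bold(sp)
#' dim(b$values)  # 4 x 100
#' @export
sample_bold <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  model <- spec$correlation
  n <- length(model$node_ids)
  t_len <- spec$n_frames
  half <- correlation_sqrt(model)
  x <- with_seed(spec$seed, {
    eps <- matrix(stats::rnorm(n * t_len), n, t_len)
    if (spec$temporal_model == "iid") {
      half %*% eps
    } else {
      a <- spec$ar_coefficient
      out <- matrix(0, n, t_len)
      out[, 1L] <- half %*% eps[, 1L]
      innov <- sqrt(1 - a^2) * (half %*% eps)
      for (t in 2L:t_len) out[, t] <- a * out[, t - 1L] + innov[, t]
      out
    }
  })
  bold_matrix(x, node_ids = model$node_ids)
}

# Symmetric PSD square root via the cached eigensystem.
correlation_sqrt <- function(model) {
  model$vectors %*% (sqrt(pmax(model$values, 0)) * t(model$vectors))
}

# Spectral pseudo-inverse square root; eigenvalues below `floor` dropped.
correlation_isqrt <- function(model, floor = 1e-10) {
  vals <- model$values
  inv <- ifelse(vals > floor, 1 / sqrt(vals), 0)
  model$vectors %*% (inv * t(model$vectors))
}
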