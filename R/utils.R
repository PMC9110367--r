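# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Pearson correlation between the upper triangles (diagonal excluded) of two
# square matrices -- the similarity convention used for all FC comparisons.
fc_similarity <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)),
            nrow(a) == ncol(a))
  ut <- upper.tri(a)
  stats::cor(a[ut], b[ut])
}

# Asymptotic two-sided Kolmogorov p-value: P(sqrt(n) D > x).
kolmogorov_pvalue <- function(stat, n) {
  x <- sqrt(n) * stat
  if (x < 1e-8) return(1)
  k <- seq_len(100L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(1, max(0, p))
}

stop_invalid <- function(...) {
  stop(structure(class = c("edgenull_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
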