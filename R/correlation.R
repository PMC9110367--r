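#' Specify a synthetic node correlation matrix
#'
#' A `correlation_spec` describes how to construct an N x N node
#' functional-connectivity (nFC) matrix for the static Gaussian null model.
#' Four kinds are supported:
#'
#' * `"identity"` -- uncorrelated nodes.
#' * `"modular"` -- a planted-partition structure: correlation `rho_within`
#'   inside each module, `rho_between` across modules. With
#'   `rho_between = 0` the matrix is block diagonal and a uniform block of
#'   size m has leading eigenvalue `1 + (m - 1) * rho_within`, so larger
#'   modules produce larger eigenvalues (and hence heavier RSS tails).
#' * `"random_factor"` -- a random low-rank-plus-diagonal covariance
#'   rescaled to a correlation matrix, giving unstructured but valid nFC.
#' * `"explicit"` -- a user-supplied symmetric matrix, validated and (for
#'   tiny negative eigenvalues) repaired.
#'
#' @param n_nodes Number of nodes N (>= 1).
#' @param kind One of `"identity"`, `"modular"`, `"random_factor"`,
#'   `"explicit"`.
#' @param module_sizes Integer vector of module sizes summing to `n_nodes`
#'   (modular only).
#' @param rho_within Within-module correlation in `[0, 1)` (modular only).
#' @param rho_between Between-module correlation in `(-1, 1)` (modular only).
#' @param n_factors Number of latent factors (random_factor only).
#' @param matrix Explicit symmetric matrix (explicit only).
#' @param seed Integer seed for the random_factor draw.
#' @return An object of class `correlation_spec`.
#' @seealso [build_correlation()]
#' @export
correlation_spec <- function(n_nodes,
                             kind = c("identity", "modular", "random_factor",
                                      "explicit"),
                             module_sizes = NULL, rho_within = NULL,
                             rho_between = 0, n_factors = NULL,
                             matrix = NULL, seed = NULL) {
  kind <- match.arg(kind)
  n_nodes <- as.integer(n_nodes)
  if (length(n_nodes) != 1L || is.na(n_nodes) || n_nodes < 1L)
    stop_invalid("n_nodes must be a positive integer")
  if (kind == "modular") {
    if (is.null(module_sizes) || is.null(rho_within))
      stop_invalid("modular spec needs module_sizes and rho_within")
    module_sizes <- as.integer(module_sizes)
    if (any(module_sizes < 1L) || sum(module_sizes) != n_nodes)
      stop_invalid("module_sizes must be positive and sum to n_nodes (",
                   n_nodes, "), got sum ", sum(module_sizes))
    if (rho_within < 0 || rho_within >= 1)
      stop_invalid("rho_within must lie in [0, 1)")
    if (abs(rho_between) >= 1)
      stop_invalid("rho_between must lie in (-1, 1)")
  }
  if (kind == "random_factor") {
    if (is.null(n_factors) || n_factors < 1L)
      stop_invalid("random_factor spec needs n_factors >= 1")
    n_factors <- as.integer(n_factors)
  }
  if (kind == "explicit") {
    if (is.null(matrix) || !is.matrix(matrix) ||
        !all(dim(matrix) == c(n_nodes, n_nodes)))
      stop_invalid("explicit spec needs an n_nodes x n_nodes matrix")
  }
  structure(list(n_nodes = n_nodes, kind = kind,
                 module_sizes = module_sizes, rho_within = rho_within,
                 rho_between = rho_between, n_factors = n_factors,
                 matrix = matrix, seed = seed),
            class = "correlation_spec")
}

#' Build a correlation model from a spec or a matrix
#'
#' Constructs the nFC matrix described by a [correlation_spec()] (or
#' validates a plain matrix) and caches its eigendecomposition
#' `R = U Lambda U'` with eigenvalues sorted in descending order. The
#' eigensystem drives every spectral quantity downstream: the Gamma-mixture
#' RSS null uses the eigenvalues, the alignment diagnostics use the
#' eigenvectors.
#'
#' Explicit matrices whose smallest eigenvalue lies in `(-1e-8, 0)` are
#' repaired by clipping to zero and rescaling back to unit diagonal; more
#' negative eigenvalues are rejected as genuinely non-PSD.
#'
#' @param spec A [correlation_spec()], or a symmetric numeric matrix
#'   (treated as an explicit spec).
#' @param node_ids Optional character vector of node labels.
#' @return An object of class `correlation_model` with elements `R`
#'   (the matrix), `values` (eigenvalues, descending), `vectors`
#'   (orthonormal eigenvectors, sign convention: largest-magnitude component
#'   positive), `node_ids`, and `spec`.
#' @examples
#' m <- build_correlation(correlation_spec(6, "modular",
#'                                         module_sizes = c(3, 3),
#'                                         rho_within = 0.5))
#' m$values[1]  # leading eigenvalue 1 + 2 * 0.5 = 2
#' @export
build_correlation <- function(spec, node_ids = NULL) {
  if (is.matrix(spec))
    spec <- correlation_spec(nrow(spec), "explicit", matrix = spec)
  stopifnot(inherits(spec, "correlation_spec"))
  n <- spec$n_nodes
  R <- switch(spec$kind,
    identity = diag(n),
    modular = {
      block <- rep.int(seq_along(spec$module_sizes), spec$module_sizes)
      same <- outer(block, block, "==")
      R <- ifelse(same, spec$rho_within, spec$rho_between)
      diag(R) <- 1
      R
    },
    random_factor = with_seed(spec$seed %||% 1L, {
      L <- matrix(stats::rnorm(n * spec$n_factors), n, spec$n_factors)
      S <- tcrossprod(L) + diag(stats::runif(n, 0.5, 1.5))
      stats::cov2cor(S)
    }),
    explicit = {
      M <- spec$matrix
      if (max(abs(M - t(M))) > 1e-8)
        stop_invalid("explicit correlation matrix is not symmetric")
      M <- (M + t(M)) / 2
      if (max(abs(diag(M) - 1)) > 1e-6)
        stop_invalid("explicit correlation matrix must have unit diagonal")
      M
    })
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    stop_invalid("correlation matrix is not positive semi-definite ",
                 "(smallest eigenvalue ", format(min(eg$values)), ")")
  if (min(eg$values) < 0) {
    # PSD repair: clip floating-point-negative eigenvalues, renormalise.
    vals <- pmax(eg$values, 0)
    R <- eg$vectors %*% (vals * t(eg$vectors))
    R <- stats::cov2cor(R)
    eg <- eigen(R, symmetric = TRUE)
  }
  vectors <- apply(eg$vectors, 2L, fix_eigvec_sign)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  structure(list(R = R, values = eg$values, vectors = vectors,
                 node_ids = node_ids, spec = spec),
            class = "correlation_model")
}

# Deterministic eigenvector sign: largest-|component| positive, ties by
# lowest index (the spectral quantities themselves are sign-invariant).
fix_eigvec_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.correlation_model <- function(x, ...) {
  cat("correlation_model:", length(x$node_ids), "nodes, kind:",
      x$spec$kind, "\n")
  cat("  eigenvalues: [", format(max(x$values), digits = 4), "...",
      format(min(x$values), digits = 4), "], sum =",
      format(sum(x$values), digits = 6), "\n")
  invisible(x)
}

# Coerce a plain matrix into a correlation_model when convenient.
as_correlation_model <- function(r) {
  if (inherits(r, "correlation_model")) r else build_correlation(r)
}
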