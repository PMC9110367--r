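#' k-means edge communities from an eFC matrix
#'
#' Clusters the rows of an (empirical or predicted) eFC matrix with k-means
#' under the Euclidean metric. Each restart draws plus-plus-style initial
#' centres (first centre uniform, subsequent centres with probability
#' proportional to squared distance from the nearest chosen centre); the
#' best of `n_restarts` solutions by total within-cluster inertia is
#' returned. Deterministic given `seed`.
#'
#' @param efc An [edge_fc()] / [predict_efc()] result or plain E x E
#'   matrix.
#' @param k Number of communities (default 10).
#' @param n_restarts Number of seeded restarts (default 20).
#' @param seed Integer RNG seed.
#' @return An object of class `community_labels`: list with `labels`
#'   (length-E integer vector in 1..k), `k`, `inertia`, `seed`,
#'   `edge_set` (NULL for plain-matrix input), `consensus = FALSE`.
#' @export
cluster_edges <- function(efc, k = 10L, n_restarts = 20L, seed = 1L) {
  es <- NULL
  if (inherits(efc, "edge_fc_matrix")) {
    es <- efc$edge_set
    efc <- efc$values
  }
  stopifnot(is.matrix(efc))
  k <- as.integer(k)
  if (k < 2L) stop_invalid("k must be at least 2")
  if (k > nrow(efc))
    stop_invalid("k = ", k, " exceeds the number of edges ", nrow(efc))
  fit <- with_seed(seed, {
    best <- NULL
    for (rep in seq_len(n_restarts)) {
      centres <- kmeanspp_init(efc, k)
      km <- suppressWarnings(
        stats::kmeans(efc, centers = centres, iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  structure(list(labels = as.integer(fit$cluster), k = k,
                 inertia = fit$tot.withinss, seed = seed,
                 edge_set = es, consensus = FALSE),
            class = "community_labels")
}

# Plus-plus seeding: spread initial centres by squared-distance sampling.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centres <- integer(k)
  centres[1L] <- sample.int(n, 1L)
  d2 <- colSums((t(x) - x[centres[1L], ])^2)
  for (i in seq_len(k - 1L)) {
    probs <- d2 / sum(d2)
    centres[i + 1L] <- sample.int(n, 1L, prob = probs)
    d2 <- pmin(d2, colSums((t(x) - x[centres[i + 1L], ])^2))
  }
  x[centres, , drop = FALSE]
}

#' Optimally match two community labellings
#'
#' Finds the label permutation of `b` maximising the number of edges with
#' matching labels (an assignment problem on the k x k contingency table,
#' solved exactly with the Hungarian algorithm), and returns the matched
#' agreement fraction. Using optimal rather than greedy matching makes the
#' agreement independent of arbitrary label order.
#'
#' @param a,b Two `community_labels` over the same edge set with the same
#'   k.
#' @return A list with `permutation` (`permutation[l]` is the a-label
#'   assigned to b-label l), `agreement` (fraction in `[0, 1]`), and
#'   `relabelled` (b's labels carried into a's label space).
#' @export
match_labels <- function(a, b) {
  la <- if (inherits(a, "community_labels")) a$labels else as.integer(a)
  lb <- if (inherits(b, "community_labels")) b$labels else as.integer(b)
  if (length(la) != length(lb))
    stop_invalid("labellings cover different edge sets (",
                 length(la), " vs ", length(lb), " edges)")
  k <- max(la, lb)
  if (inherits(a, "community_labels") && inherits(b, "community_labels") &&
      a$k != b$k)
    stop_invalid("labellings have different k")
  counts <- matrix(0, k, k)
  tab <- table(factor(la, levels = seq_len(k)),
               factor(lb, levels = seq_len(k)))
  counts[] <- as.numeric(tab)
  perm <- hungarian_max(counts)
  relabelled <- perm[lb]
  list(permutation = perm,
       agreement = mean(relabelled == la),
       relabelled = relabelled)
}

# Exact linear assignment (maximisation) via the Hungarian algorithm with
# dual potentials and shortest augmenting paths; O(k^3).
hungarian_max <- function(benefit) {
  cost <- max(benefit) - benefit
  n <- nrow(cost)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)           # p[j+1]: row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0L:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  # p[j+1] = row assigned to column j: permutation mapping b-label j -> a-label
  perm <- integer(n)
  perm[seq_len(n)] <- p[-1L]
  perm
}

#' Consensus labelling across runs or subjects
#'
#' Aligns every run to the first via [match_labels()] and assigns each edge
#' its modal (most common) aligned label, ties broken by the lowest label.
#'
#' @param runs List of `community_labels` with identical edge sets and k.
#' @return A `community_labels` with `consensus = TRUE`.
#' @export
consensus_labels <- function(runs) {
  stopifnot(length(runs) >= 1L)
  ks <- vapply(runs, function(r) r$k, integer(1))
  if (length(unique(ks)) != 1L)
    stop_invalid("runs have differing k: ", paste(unique(ks), collapse = ", "))
  ref <- runs[[1L]]
  aligned <- vapply(runs, function(r) match_labels(ref, r)$relabelled,
                    integer(length(ref$labels)))
  modal <- apply(aligned, 1L, function(row) {
    tt <- tabulate(row, nbins = ks[1L])
    which.max(tt)   # ties -> lowest label
  })
  structure(list(labels = as.integer(modal), k = ref$k,
                 inertia = NA_real_, seed = ref$seed,
                 edge_set = ref$edge_set, consensus = TRUE),
            class = "community_labels")
}

#' Node-level edge-cluster similarity
#'
#' Reshapes the edge labels into an N x N label matrix L (L[i, j] = label
#' of edge (i, j)) and scores each node pair (i, j) by the fraction of
#' shared targets m (m != i, j) whose edges carry the same label:
#' `sum_m [L[i, m] == L[j, m]] / (N - 2)`. The self-columns i and j are
#' excluded because the diagonal of the label matrix is undefined.
#'
#' @param labels A `community_labels` whose `edge_set` is set (i.e. built
#'   from an eFC with edge metadata), or a list with `labels` and
#'   `edge_set`.
#' @param n_nodes Number of nodes; inferred from the edge set when absent.
#' @return An object of class `edge_cluster_similarity`: an N x N
#'   symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
edge_cluster_similarity <- function(labels, n_nodes = NULL) {
  stopifnot(inherits(labels, "community_labels"))
  es <- labels$edge_set
  if (is.null(es)) {
    if (is.null(n_nodes))
      stop_invalid("labels carry no edge set; supply n_nodes")
    es <- edge_set(n_nodes)
    if (nrow(es) != length(labels$labels))
      stop_invalid("n_nodes inconsistent with the number of edges")
  }
  n <- max(es$j)
  if (n < 3L) stop_invalid("need at least 3 nodes")
  lab_mat <- matrix(NA_integer_, n, n)
  lab_mat[cbind(es$i, es$j)] <- labels$labels
  lab_mat[cbind(es$j, es$i)] <- labels$labels
  sim <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m <- setdiff(seq_len(n), c(i, j))
      sim[i, j] <- sim[j, i] <-
        sum(lab_mat[i, m] == lab_mat[j, m]) / (n - 2L)
    }
  }
  structure(sim, class = c("edge_cluster_similarity", class(sim)))
}
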