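test_that("z-scoring centres, rescales, and is idempotent", {
  set.seed(1)
  x <- matrix(rnorm(5 * 100, mean = 3, sd = 2), 5, 100)
  b <- zscore_bold(x)
  expect_lt(max(abs(rowMeans(b$z_values))), 1e-10)
  # population convention: row variance with denominator T is exactly 1
  expect_equal(rowSums(b$z_values^2) / 100, rep(1, 5), tolerance = 1e-12)
  # affine invariance: z row perfectly correlated with raw row
  for (i in 1:5) expect_equal(cor(b$z_values[i, ], x[i, ]), 1,
                              tolerance = 1e-12)
  # idempotence
  b2 <- zscore_bold(b$z_values)
  expect_equal(b2$z_values, b$z_values, tolerance = 1e-12)
  # constant row names the offending node
  bad <- x; bad[3, ] <- 7
  expect_error(zscore_bold(bad), "n3")
})

test_that("edge set enumerates N(N-1)/2 lexicographic pairs with index map", {
  es <- edge_set(5)
  expect_equal(nrow(es), 10)
  expect_true(all(es$i < es$j))
  expect_identical(es$i[1:4], rep(1L, 4))      # lexicographic order
  expect_equal(nrow(edge_set(200)), 19900)
  # pair -> index -> pair round trip, order-insensitive
  idx <- edge_index(es, es$j, es$i)
  expect_identical(idx, seq_len(10L))
  expect_error(edge_index(es, 2, 2), "self-pairs")
})

test_that("edge time series are frame-wise products with exact nFC means", {
  # hand product: z1 = (1,-1), z2 = (1,-1) -> single edge row (1, 1)
  z <- rbind(c(1, -1), c(1, -1))
  expect_equal(as.numeric(edge_time_series(z)$values), c(1, 1))
  # duplicated node: edge row is z^2, nonnegative
  set.seed(2)
  zr <- matrix(rnorm(20), 2, 10)
  zdup <- rbind(zr, zr[1, ])
  ets <- edge_time_series(zscore_bold(zdup)$z_values)
  e13 <- edge_index(ets$edge_set, 1, 3)
  expect_true(all(ets$values[e13, ] >= 0))
  # time means reproduce the Pearson nFC exactly under population z-scores
  x <- matrix(rnorm(4 * 50), 4, 50)
  b <- zscore_bold(x)
  ets <- edge_time_series(b)
  R <- cor(t(x))
  expect_equal(unname(rowMeans(ets$values)),
               R[cbind(ets$edge_set$i, ets$edge_set$j)],
               tolerance = 1e-12)
})

test_that("edge FC is a unit-diagonal normalised inner product", {
  set.seed(3)
  b <- zscore_bold(matrix(rnorm(4 * 20), 4, 20))
  ets <- edge_time_series(b)
  g <- edge_fc(ets)
  expect_equal(unname(diag(g$values)), rep(1, 6), tolerance = 1e-12)
  expect_equal(g$values, t(g$values))
  expect_true(all(abs(g$values) <= 1 + 1e-12))
  # brute-force double-loop oracle
  E <- nrow(ets$values)
  brute <- matrix(0, E, E)
  for (e in 1:E) for (f in 1:E) {
    num <- sum(ets$values[e, ] * ets$values[f, ])
    brute[e, f] <- num / (sqrt(sum(ets$values[e, ]^2)) *
                          sqrt(sum(ets$values[f, ]^2)))
  }
  expect_equal(g$values, brute, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("sign-flipping one node gives perfectly anticorrelated edges", {
  set.seed(4)
  zr <- zscore_bold(matrix(rnorm(2 * 30), 2, 30))$z_values
  z3 <- rbind(zr, -zr[1, ])   # node 3 = -node 1
  g <- edge_fc(edge_time_series(z3))
  es <- edge_set(3)
  e12 <- edge_index(es, 1, 2); e23 <- edge_index(es, 2, 3)
  expect_equal(g$values[e12, e23], -1, tolerance = 1e-12)
})

test_that("RSS conventions follow their closed forms", {
  set.seed(5)
  z <- zscore_bold(matrix(rnorm(6 * 40), 6, 40))$z_values
  # all-pairs RSS is exactly the squared frame norm
  expect_equal(as.numeric(rss(z, "all_pairs")), colSums(z^2),
               tolerance = 1e-12)
  # brute-force sum over all N^2 edge squares per frame
  brute <- sapply(seq_len(ncol(z)), function(t)
    sqrt(sum(outer(z[, t], z[, t])^2)))
  expect_equal(as.numeric(rss(z, "all_pairs")), brute, tolerance = 1e-10)
  # upper-triangular convention from the explicit edge matrix
  ets <- edge_time_series(z)
  expect_equal(as.numeric(rss(z)), sqrt(colSums(ets$values^2)),
               tolerance = 1e-10)
  # zero frame -> zero RSS under both conventions
  z0 <- z; z0[, 7] <- 0
  expect_equal(as.numeric(rss(z0))[7], 0)
  expect_equal(as.numeric(rss(z0, "all_pairs"))[7], 0)
  # all-ones frame -> RSS_all = N
  z1 <- z; z1[, 3] <- 1
  expect_equal(as.numeric(rss(z1, "all_pairs"))[3], 6)
})

test_that("the fourth-moment ratio shrinks with N as 3/N for Gaussians", {
  expect_equal(kurtosis_ratio(matrix(rnorm(50), 1, 50)), 1) # single node
  m10 <- build_correlation(correlation_spec(10, "identity"))
  m100 <- build_correlation(correlation_spec(100, "identity"))
  r10 <- kurtosis_ratio(zdraw(m10, 5000, seed = 6))
  r100 <- kurtosis_ratio(zdraw(m100, 5000, seed = 6))
  expect_gt(r10, r100)
  m200 <- build_correlation(correlation_spec(200, "identity"))
  r200 <- kurtosis_ratio(zdraw(m200, 2000, seed = 6))
  expect_lt(r200, 3 * 200 / 200^2 * 1.2)   # Gaussian kurtosis bound + slack
})

test_that("binarised edges follow the sign rule and the fair-coin null", {
  # sign rule including exact-zero ties
  z <- rbind(c(1, -1, 3, 0), c(0.5, 0.2, 1, 2))
  bm <- binarize_edges(edge_time_series(z))
  expect_identical(as.integer(bm$values), c(1L, 0L, 1L, 0L))
  expect_identical(bm$tie_count, 1L)
  # perfectly correlated pair: all ones
  set.seed(7)
  zr <- matrix(rnorm(40), 2, 20); zr[2, ] <- zr[1, ]
  expect_true(all(binarize_edges(edge_time_series(zr))$values == 1))
  # independent nodes: per-edge mean ~ 1/2 within 4 binomial SEs
  t_len <- 5e4
  b <- zdraw(build_correlation(correlation_spec(4, "identity")), t_len,
             seed = 8)
  means <- rowMeans(binarize_edges(edge_time_series(b))$values)
  expect_lt(max(abs(means - 0.5)), 4 * sqrt(0.25 / t_len))
})

test_that("arcsine-law convergence of binary edge means on null data", {
  m <- modular_model(c(3, 2), rho_within = 0.6, rho_between = -0.2)
  t_len <- 5e4
  b <- zdraw(m, t_len, seed = 9)
  means <- rowMeans(binarize_edges(edge_time_series(b))$values)
  es <- edge_set(5)
  p <- bernoulli_probability(m$R[cbind(es$i, es$j)])
  expect_true(all(abs(means - p) < 3 * sqrt(p * (1 - p) / t_len) + 2e-3))
})

test_that("full-fraction reconstruction recovers the nFC exactly", {
  b <- zdraw(modular_model(), 300, seed = 10)
  out <- frame_sorted_reconstruction(b, empirical_nfc(b$values),
                                     fractions = 1)
  expect_equal(out$similarity, c(1, 1), tolerance = 1e-10)
  expect_error(frame_sorted_reconstruction(b, empirical_nfc(b$values),
                                           fractions = 1e-4),
               "zero frames")
})

test_that("high-RSS frames reconstruct the nFC better than low-RSS frames", {
  m <- modular_model(c(10, 8, 7), rho_within = 0.5)
  b <- zdraw(m, 1200, seed = 11)
  out <- frame_sorted_reconstruction(b, m, fractions = 0.05)
  expect_gt(out$similarity[out$direction == "descending"],
            out$similarity[out$direction == "ascending"])
})

test_that("eFC and the RSS multiset are frame-permutation invariant", {
  b <- zdraw(modular_model(), 200, seed = 12)
  z <- b$z_values
  perm <- sample(200)
  g1 <- edge_fc(edge_time_series(z))$values
  g2 <- edge_fc(edge_time_series(z[, perm]))$values
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_equal(sort(as.numeric(rss(z))), sort(as.numeric(rss(z[, perm]))),
               tolerance = 1e-12)
})
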