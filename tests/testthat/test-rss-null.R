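test_that("null RSS moments follow the eigenvalue closed forms", {
  d4 <- null_rss_distribution(build_correlation(correlation_spec(4,
                                                                 "identity")))
  expect_equal(null_rss_moments(d4),
               c(mean = 4 / sqrt(2), variance = 4))
  # one block of 3 at rho 0.5: spectrum (2, 0.5, 0.5), variance 4.5
  db <- null_rss_distribution(
    build_correlation(correlation_spec(3, "modular", module_sizes = 3,
                                       rho_within = 0.5)))
  expect_equal(sort(db$lambda, decreasing = TRUE), c(2, 0.5, 0.5),
               tolerance = 1e-10)
  expect_equal(unname(null_rss_moments(db)["variance"]), 4.5,
               tolerance = 1e-10)
  # mean is N / sqrt(2) for any correlation structure (trace preservation)
  for (seed in 1:3) {
    m <- random_model(7, 2, seed = seed)
    expect_equal(unname(null_rss_moments(null_rss_distribution(m))["mean"]),
                 7 / sqrt(2), tolerance = 1e-8)
  }
})

test_that("the MGF matches its product form and its moment derivatives", {
  d2 <- null_rss_distribution(c(1, 1))
  expect_equal(null_rss_mgf(d2, 0), 1)
  expect_equal(null_rss_mgf(d2, 0.1), (1 - sqrt(2) * 0.1)^(-1),
               tolerance = 1e-12)
  d <- null_rss_distribution(random_model(5, 2, seed = 31))
  h <- 1e-5
  mom <- null_rss_moments(d)
  d1 <- (null_rss_mgf(d, h) - null_rss_mgf(d, -h)) / (2 * h)
  expect_equal(d1, unname(mom["mean"]), tolerance = 1e-6)
  d2n <- (null_rss_mgf(d, h) - 2 + null_rss_mgf(d, -h)) / h^2
  expect_equal(d2n - d1^2, unname(mom["variance"]), tolerance = 1e-4)
  expect_error(null_rss_mgf(d, 1 / (sqrt(2) * max(d$lambda))),
               "undefined")
})

test_that("CDF inversion agrees with closed-form special cases", {
  # identity spectrum: sqrt(2) * RSS ~ chi-square_N
  dN <- null_rss_distribution(rep(1, 4))
  med <- qchisq(0.5, df = 4) / sqrt(2)
  expect_equal(null_rss_cdf(dN, med, method = "imhof"), 0.5,
               tolerance = 1e-5)
  grid <- qchisq(c(0.1, 0.25, 0.75, 0.9, 0.99), df = 4) / sqrt(2)
  expect_equal(null_rss_cdf(dN, grid, method = "imhof"),
               c(0.1, 0.25, 0.75, 0.9, 0.99), tolerance = 1e-5)
  # single component: exact Gamma(1/2, sqrt(2) lambda)
  d1 <- null_rss_distribution(2.5)
  x <- c(0.5, 2, 7)
  expect_equal(null_rss_cdf(d1, x),
               pgamma(x, shape = 0.5, scale = sqrt(2) * 2.5))
  # two equal components collapse to an exponential law
  d2 <- null_rss_distribution(c(1, 1))
  expect_equal(null_rss_cdf(d2, x, method = "imhof"),
               pexp(x, rate = 1 / sqrt(2)), tolerance = 1e-5)
})

test_that("cached CDF matches direct inversion and basic CDF axioms", {
  d <- null_rss_distribution(c(3, 1.5, 0.8, 0.5, 0.2))
  xs <- seq(0.1, 15, length.out = 40)
  expect_equal(null_rss_cdf(d, xs), null_rss_cdf(d, xs, method = "imhof"),
               tolerance = 2e-5)
  p <- null_rss_cdf(d, xs)
  expect_true(all(diff(p) >= 0))
  expect_equal(null_rss_cdf(d, c(-1, 0)), c(0, 0))
  expect_gt(null_rss_cdf(d, 100), 1 - 1e-8)
})

test_that("CDF agrees with a Monte-Carlo Gamma-sum oracle", {
  lambda <- c(3, 1.5, 0.8, 0.5, 0.2)
  d <- null_rss_distribution(lambda)
  n <- 2e5
  set.seed(32)
  draws <- rowSums(sapply(lambda, function(li)
    rgamma(n, shape = 0.5, scale = sqrt(2) * li)))
  for (x in quantile(draws, c(0.1, 0.5, 0.9, 0.99))) {
    p <- null_rss_cdf(d, x)
    expect_equal(mean(draws <= x), p,
                 tolerance = 3 * sqrt(p * (1 - p) / n) + 1e-6)
  }
})

test_that("null RSS sampling is seeded, unbiased, and law-identical to
           direct frame norms", {
  d <- null_rss_distribution(rep(1, 10))
  s1 <- sample_null_rss(d, 1000, seed = 33)
  expect_identical(s1, sample_null_rss(d, 1000, seed = 33))
  big <- sample_null_rss(d, 1e5, seed = 34)
  expect_equal(mean(big), 10 / sqrt(2), tolerance = 0.05)
  # two-route equivalence: Gamma sums vs ||R^(1/2) g||^2 / sqrt(2)
  m <- modular_model(c(4, 3, 3), rho_within = 0.5)
  dm <- null_rss_distribution(m)
  n <- 5e4
  route1 <- sample_null_rss(dm, n, seed = 35)
  g <- sample_bold(surrogate_spec(m, n, seed = 36))
  route2 <- colSums(g$values^2) / sqrt(2)
  ks <- suppressWarnings(ks.test(route1, route2))
  expect_lt(unname(ks$statistic), 1.628 * sqrt(2 * n / n^2))  # alpha = 0.01
})

test_that("spectrum truncation keeps the top eigenvalues and converges", {
  m <- modular_model(c(6, 4, 2), rho_within = 0.6)
  d <- null_rss_distribution(m)
  expect_equal(truncate_spectrum(d, length(d$lambda))$lambda, d$lambda)
  d1 <- truncate_spectrum(d, 1)
  expect_equal(d1$lambda, max(m$values))
  expect_equal(null_rss_cdf(d1, 3),
               pgamma(3, shape = 0.5, scale = sqrt(2) * max(m$values)))
  expect_error(truncate_spectrum(d, 0), "rank")
  # 99th-percentile error shrinks as more eigenvalues are retained
  qs <- sapply(c(1, 6, 12), function(q) {
    dq <- truncate_spectrum(d, q)
    quantile(sample_null_rss(dq, 5e4, seed = 37), 0.99)
  })
  err <- abs(qs - qs[3])
  expect_true(err[1] > err[2] && err[2] >= err[3])
})

test_that("the centred MGF obeys the subexponential quadratic bound", {
  d <- null_rss_distribution(modular_model(c(5, 3, 2), rho_within = 0.5))
  mom <- null_rss_moments(d)
  s_adm <- 1 / (4 * max(d$lambda))
  for (s in seq(-s_adm, s_adm, length.out = 9)) {
    centred <- null_rss_mgf(d, s) * exp(-s * mom["mean"])
    expect_lte(unname(centred), exp(s^2 * mom["variance"]) * (1 + 1e-12))
  }
})

test_that("larger top eigenvalue implies a heavier RSS tail", {
  # equal trace, different concentration
  da <- null_rss_distribution(c(3, 1, 1, 1))
  db <- null_rss_distribution(c(2, 2, 1, 1))
  q999 <- function(d) {
    f <- function(x) null_rss_cdf(d, x, method = "imhof") - 0.999
    uniroot(f, c(1, 60))$root
  }
  expect_gt(q999(da), q999(db))
})

test_that("KS test against the null: PIT exactness and calibration", {
  d <- null_rss_distribution(c(2, 1, 0.5))
  # observed = exact null quantiles -> D <= 1/T
  cdf_grid <- seq(0, 40, length.out = 20000)
  ps <- null_rss_cdf(d, cdf_grid)
  t_len <- 200
  qs <- approx(ps, cdf_grid, xout = (seq_len(t_len) - 0.5) / t_len)$y
  res <- ks_test_rss(structure(qs, convention = "upper_triangular"), d)
  expect_lte(res$statistic, 1 / t_len + 1e-3)
  expect_gt(res$p_value, 0.99)
  # draws from the null are not rejected; far-off draws are
  s <- sample_null_rss(d, 2000, seed = 38)
  ok <- ks_test_rss(structure(s, convention = "upper_triangular"), d)
  expect_gt(ok$p_value, 1e-4)
  bad <- ks_test_rss(structure(s * 2, convention = "upper_triangular"), d)
  expect_lt(bad$p_value, 1e-6)
  expect_true(bad$reject)
  # Bonferroni decision at family level
  res_b <- ks_test_rss(structure(s, convention = "upper_triangular"), d,
                       n_subjects_for_bonferroni = 100)
  expect_false(is.na(res_b$reject_bonferroni))
  expect_warning(ks_test_rss(structure(s[1:5],
                                       convention = "upper_triangular"), d),
                 "unreliable")
})

test_that("the RSS marginal law is blind to temporal order", {
  # AR(1) surrogates share the stationary spatial covariance R, so their
  # per-frame RSS has exactly the null marginal law; the KS distance to the
  # null CDF vanishes with T even under strong serial dependence. (The KS
  # *p-value* is not nominal under dependence -- serial correlation inflates
  # the statistic's sampling variability -- so the marginal-law check is on
  # the distance itself.)
  m <- modular_model(c(6, 6), rho_within = 0.5)
  d <- null_rss_distribution(m)
  t_len <- 1e5
  for (seed in 1:2) {
    b <- sample_bold(surrogate_spec(m, t_len, "ar1", ar_coefficient = 0.9,
                                    seed = seed))
    v <- structure(colSums(b$values^2), convention = "all_pairs")
    # dependent-sample fluctuation scale: sqrt((1+a^2)/(1-a^2)) / sqrt(T)
    expect_lt(ks_test_rss(v, d)$statistic, 0.022)
  }
})
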