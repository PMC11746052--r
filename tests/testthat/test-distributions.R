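test_that("survival functions match their closed forms and the density", {
  # gamma survival vs direct quadrature of the gamma density (oracle
  # written out, independent of the package's evaluation path)
  m <- parsurv("gamma", shape = 1.6860, rate = 0.0743)
  dens <- function(u) 0.0743^1.686 * u^(1.686 - 1) * exp(-0.0743 * u) /
    gamma(1.686)
  oracle <- stats::integrate(dens, 12, Inf, rel.tol = 1e-12)$value
  expect_equal(psurv(m, 12), oracle, tolerance = 1e-8)

  # log-logistic closed form: S(scale) = 1/2 by construction
  ll <- parsurv("loglogistic", shape = 1.6860, scale = 17.8960)
  expect_equal(psurv(ll, 17.8960), 0.5, tolerance = 1e-12)
  expect_equal(psurv(ll, 30), 1 / (1 + (30 / 17.896)^1.686), tolerance = 1e-12)

  # Gompertz closed form
  gz <- parsurv("gompertz", shape = 0.08, rate = 0.03)
  expect_equal(psurv(gz, 10), exp(-(0.03 / 0.08) * (exp(0.08 * 10) - 1)),
               tolerance = 1e-12)

  # S(0) = 1 for every family
  for (m in recovery_models()) expect_equal(psurv(m, 0), 1)
})

test_that("survival curves are monotone, bounded, and quantiles round-trip", {
  grid <- seq(0, 120, by = 0.5)
  for (m in tbl_models()) {
    s <- psurv(m, grid)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12))
    # quantile round trip at interior times
    tt <- c(1, 5, 12, 36, 90)
    expect_equal(qsurv(m, psurv(m, tt)), tt, tolerance = 1e-6)
  }
})

test_that("generalized gamma nests Weibull and lognormal at its limits", {
  mu <- 2.314; sigma <- 0.955
  t <- c(0.5, 2, 8, 20, 60)
  gg1 <- parsurv("gengamma_prentice", mu = mu, sigma = sigma, Q = 1)
  wb <- parsurv("weibull_aft", shape = 1 / sigma, scale = exp(mu))
  expect_equal(psurv(gg1, t), psurv(wb, t), tolerance = 1e-8)
  # Q -> 0 limit is lognormal; the deviation is first order in Q, so the
  # error at Q = +/-1e-5 is bounded by |Q| and shrinks linearly with Q
  ln <- parsurv("lognormal", meanlog = mu, sdlog = sigma)
  err <- function(q) {
    gg0 <- parsurv("gengamma_prentice", mu = mu, sigma = sigma, Q = q)
    max(abs(psurv(gg0, t) - psurv(ln, t)))
  }
  for (q in c(1e-5, -1e-5)) expect_lt(err(q), 1e-5)
  expect_lt(err(1e-5), err(1e-3) / 50)
})

test_that("AFT and PH Weibull parameterizations are the same law", {
  s <- 1.62; b <- 14.3
  aft <- parsurv("weibull_aft", shape = s, scale = b)
  ph <- parsurv("weibull_ph", shape = s, rate = b^(-s))
  t <- seq(0.1, 100, length.out = 50)
  expect_equal(psurv(aft, t), psurv(ph, t), tolerance = 1e-12)
  expect_equal(dsurv(aft, t), dsurv(ph, t), tolerance = 1e-12)
})

test_that("median survival agrees between closed form and root finding", {
  expect_equal(median_survival(parsurv("exponential", rate = 0.2)),
               log(2) / 0.2, tolerance = 1e-10)
  expect_equal(median_survival(parsurv("loglogistic", shape = 2.347,
                                       scale = 7.678)), 7.678)
  # generalized gamma with negative Q: quantile path vs bisection on S(t)
  gg <- parsurv("gengamma_prentice", mu = 2.3140, sigma = 0.9550,
                Q = -0.8350)
  expect_equal(median_survival(gg), median_survival(gg, method = "root"),
               tolerance = 1e-6)
  expect_equal(psurv(gg, median_survival(gg)), 0.5, tolerance = 1e-8)
})

test_that("random sampling matches the analytic law and is reproducible", {
  m <- parsurv("loglogistic", shape = 2.347, scale = 7.678)
  x <- rsurv(m, 10000, seed = 42)
  expect_identical(x, rsurv(m, 10000, seed = 42))
  # Kolmogorov-Smirnov distance against the analytic CDF
  ks <- max(abs(stats::ecdf(x)(sort(x)) - (1 - psurv(m, sort(x)))))
  expect_lt(ks, 0.02)
  ex <- rsurv(parsurv("exponential", rate = 1), 1e5, seed = 7)
  expect_lt(abs(mean(ex) - 1), 3 / sqrt(1e5))
})

test_that("domain and parameter validation throw informative errors", {
  m <- parsurv("exponential", rate = 0.1)
  expect_error(psurv(m, -1), "non-negative")
  expect_error(parsurv("weibull_aft", shape = -1, scale = 2),
               "strictly positive")
  expect_error(parsurv("gengamma_prentice", mu = 1, sigma = 0, Q = 0.5),
               "strictly positive")
  # Q may be any real, including the printed negative value
  expect_s3_class(parsurv("gengamma_prentice", mu = 2.314, sigma = 0.955,
                          Q = -0.835), "parsurv")
  expect_error(parsurv("loglogistic", shape = 1), "requires parameters")
})
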