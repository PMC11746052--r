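test_that("exponential MLE has its closed form", {
  set.seed(1)
  tt <- stats::rexp(200, 0.08)
  f <- fit_parsurv(tt, rep(1, 200), "exponential")
  expect_equal(unname(coef(f)), 200 / sum(tt), tolerance = 1e-12)
  # with censoring: events / total exposure
  ev <- as.integer(tt < 15)
  f2 <- fit_parsurv(pmin(tt, 15), ev, "exponential")
  expect_equal(unname(coef(f2)), sum(ev) / sum(pmin(tt, 15)),
               tolerance = 1e-12)
})

test_that("simulation recovery: fitted parameters approach the truth", {
  m <- parsurv("loglogistic", shape = 2.347, scale = 7.678)
  x <- rsurv(m, 500, seed = 5)
  f <- fit_parsurv(x, rep(1, 500), "loglogistic")
  expect_lt(max(abs(coef(f) - m$params) / m$params), 0.10)
})

test_that("the fitted optimum dominates the generating parameters", {
  for (nm in c("weibull_aft", "gamma", "lognormal", "loglogistic")) {
    m <- recovery_models()[[nm]]
    x <- rsurv(m, 300, seed = 9)
    ev <- rep(1, 300)
    f <- fit_parsurv(x, ev, nm)
    expect_gte(f$loglik, parsurv_loglik(m, x, ev) - 1e-6)
  }
})

test_that("our maximum likelihood agrees with flexsurvreg", {
  m <- parsurv("weibull_aft", shape = 1.5, scale = 20)
  set.seed(13)
  tt <- rsurv(m, 400)
  cens <- stats::runif(400, 0, 80)
  d <- data.frame(time = pmin(tt, cens), event = as.integer(tt <= cens))
  ours <- fit_parsurv(d$time, d$event, "weibull_aft")
  ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = d,
                               dist = "weibull")
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-6)
  expect_equal(unname(coef(ours)), unname(ref$res[c("shape", "scale"), "est"]),
               tolerance = 1e-4)
})

test_that("information criteria follow their closed forms", {
  expect_equal(information_criteria(-100, 2, 50)[["AIC"]], 204)
  expect_equal(information_criteria(-100, 2, 100)[["BIC"]],
               2 * log(100) + 200)
  expect_equal(information_criteria(-100, 2, 100)[["BIC"]], 209.2103,
               tolerance = 1e-4)
  # one extra parameter at equal likelihood costs exactly 2 AIC points
  expect_equal(information_criteria(-50, 3, 30)[["AIC"]] -
               information_criteria(-50, 2, 30)[["AIC"]], 2)
  expect_error(information_criteria(-10, 0, 5))
})

test_that("model selection prefers low AIC with BIC and parsimony ties", {
  fake <- function(family, loglik, converged = TRUE)
    psmcea:::new_parsurv_fit(
      structure(list(family = family, params = c(rate = 1),
                     time_unit = "months"), class = "parsurv"),
      loglik, time = rep(1, 100), event = rep(1, 100),
      converged = converged, family = family)
  fs <- structure(list(fits = list(
    loglogistic = fake("loglogistic", -1413.186 / 2 + 2),  # AIC 1413.186
    gamma = fake("gamma", -1421.216 / 2 + 2)),             # AIC 1421.216
    n = 100), class = "parsurv_fitset")
  expect_equal(select_best(fs), "loglogistic")

  # equal AIC: lower BIC wins; gengamma's third parameter costs it the tie
  fs2 <- structure(list(fits = list(
    gengamma_prentice = fake("gengamma_prentice", -100 - 3),  # AIC 206
    weibull_aft = fake("weibull_aft", -100 - 2)),             # AIC 204
    n = 100), class = "parsurv_fitset")
  expect_equal(select_best(fs2), "weibull_aft")

  # single converged family is selected outright
  fs3 <- structure(list(fits = list(
    gamma = fake("gamma", -80),
    lognormal = fake("lognormal", -10, converged = FALSE)),
    n = 100), class = "parsurv_fitset")
  expect_equal(select_best(fs3), "gamma")
  fs4 <- structure(list(fits = list(
    gamma = fake("gamma", -80, converged = FALSE)), n = 100),
    class = "parsurv_fitset")
  expect_error(select_best(fs4), "no converged")
})

test_that("selection identifies the generating family in most replicates", {
  # well-separated pair: exponential vs log-logistic, n = 300
  hits <- 0
  for (s in 1:50) {
    m <- parsurv("loglogistic", shape = 2.2, scale = 8)
    x <- rsurv(m, 300, seed = 1000 + s)
    fs <- fit_parsurv_set(x, rep(1, 300),
                          families = c("exponential", "loglogistic"))
    hits <- hits + (select_best(fs) == "loglogistic")
  }
  expect_gte(hits / 50, 0.7)
})

test_that("the fit report table satisfies the AIC/BIC identities", {
  m <- parsurv("gamma", shape = 1.7, rate = 0.08)
  x <- rsurv(m, 150, seed = 21)
  fs <- fit_parsurv_set(x, rep(1, 150),
                        families = c("exponential", "gamma", "weibull_aft"))
  tab <- as.data.frame(fs)
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$loglik)
  expect_equal(tab$BIC, tab$k * log(150) - 2 * tab$loglik)
  expect_true(all(tab$converged))
})
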