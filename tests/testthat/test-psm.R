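test_that("occupancy is conserved and deaths accumulate monotonically", {
  tm <- tbl_models()
  pairs <- list(c("os_pembro_whole", "pfs_pembro_whole"),
                c("os_chemo_whole", "pfs_chemo_whole"),
                c("os_pembro_nonepi", "pfs_pembro_nonepi"),
                c("os_chemo_nonepi", "pfs_chemo_nonepi"),
                c("os_pembro_epi", "pfs_pembro_epi"),
                c("os_chemo_epi", "pfs_chemo_epi"))
  for (p in pairs) {
    tr <- build_trace(tm[[p[1]]], tm[[p[2]]])
    expect_lt(max(abs(tr$pfs + tr$pd + tr$dead - 1)), 1e-12)
    expect_true(all(tr$pd >= 0))
    expect_true(all(diff(tr$dead) >= 0))
    expect_equal(unlist(tr[1, c("pfs", "pd", "dead")]),
                 c(pfs = 1, pd = 0, dead = 0))
  }
})

test_that("the progressed compartment is clamped when PFS crosses OS", {
  # a slow PFS curve against fast mortality forces S_PFS > S_OS
  os <- parsurv("exponential", rate = 0.2)
  pfs <- parsurv("exponential", rate = 0.01)
  tr <- build_trace(os, pfs)
  expect_true(all(tr$pd >= 0))
  cross <- tr$pfs < psurv(pfs, tr$cycle)
  expect_true(any(cross))
  expect_equal(tr$pfs[cross], psurv(os, tr$cycle[cross]))
})

test_that("trace occupancies equal direct survival evaluations", {
  tm <- tbl_models()
  tr <- build_trace(tm$os_pembro_whole, tm$pfs_pembro_whole)
  k <- 87  # an arbitrary interior boundary
  s_os <- psurv(tm$os_pembro_whole, k)
  s_pfs <- psurv(tm$pfs_pembro_whole, k)
  row <- tr[tr$cycle == k, ]
  expect_equal(row$pfs, min(s_pfs, s_os), tolerance = 1e-12)
  expect_equal(row$pd, s_os - min(s_pfs, s_os), tolerance = 1e-12)
  expect_equal(row$dead, 1 - s_os, tolerance = 1e-12)
  # month-grid interpretation evaluates at calendar months instead
  trm <- build_trace(tm$os_pembro_whole, tm$pfs_pembro_whole,
                     time_unit = "months")
  expect_equal(trm$dead[trm$cycle == k],
               1 - psurv(tm$os_pembro_whole, k * 21 / 30.4375),
               tolerance = 1e-12)
  expect_error(build_trace(tm$os_pembro_whole, tm$pfs_pembro_whole,
                           horizon_years = 0), "positive")
})

test_that("discount factors follow the closed form in both conventions", {
  expect_equal(discount_factor(1, 0.05, "continuous"), 1 / 1.05)
  expect_equal(discount_factor(1, 0.05, "continuous"), 0.952381,
               tolerance = 1e-6)
  expect_equal(discount_factor(10, 0.05, "continuous"), 0.613913,
               tolerance = 1e-6)
  expect_equal(discount_factor(c(0, 3, 17.2), 0), rep(1, 3))
  # annual stepping holds the factor constant within each year
  expect_equal(discount_factor(c(0.2, 0.99), 0.05, "annual"), c(1, 1))
  expect_equal(discount_factor(1.5, 0.05, "annual"), 1 / 1.05)
  expect_error(discount_factor(1, -0.01), "rate")
  expect_error(discount_factor(-1, 0.05), ">= 0")
})

test_that("QALY accrual: state utilities, half-cycle and the AE decrement", {
  cfg <- load_cfg("whole")
  eng <- psmcea:::prepare_engines(cfg)
  pars <- baseline_pars(cfg)
  # switching off disutilities raises QALYs by exactly the one-off
  # first-cycle decrement sum(incidence x disutility) x cycle-years
  pars0 <- pars
  pars0$ae_disutilities[] <- 0
  a_with <- psmcea:::evaluate_arm(eng$pembro_chemo, pars)
  a_without <- psmcea:::evaluate_arm(eng$pembro_chemo, pars0)
  dec <- sum(pars$ae_incidence$pembro_chemo *
             pars$ae_disutilities[names(pars$ae_incidence$pembro_chemo)])
  expect_equal(dec, 0.135428, tolerance = 1e-6)  # hand-summed AE burden
  expect_equal(a_without$qaly - a_with$qaly, dec * 21 / 365.25,
               tolerance = 1e-12)
  # unit utilities and no AEs: QALYs equal discounted life-years exactly
  pars1 <- pars0
  pars1$utility_pfs <- 1; pars1$utility_pd <- 1
  a_unit <- psmcea:::evaluate_arm(eng$pembro_chemo, pars1)
  expect_equal(a_unit$qaly, a_unit$ly, tolerance = 1e-12)
})

test_that("a cohort held in PFS accrues utility times time", {
  # ~immortal, non-progressing cohort over a 10-cycle horizon, no
  # discounting: QALYs = u_pfs x horizon
  cfg <- load_cfg("whole")
  cfg$discount_rate <- 0
  cfg$horizon_years <- 10 * 21 / 365.25  # exactly 10 cycles
  immortal <- list(family = "exponential", rate = 1e-12)
  cfg$arms$pembro_chemo$os <- immortal
  cfg$arms$pembro_chemo$pfs <- immortal
  pars <- baseline_pars(cfg)
  pars$ae_disutilities[] <- 0
  pars$discount_rate <- 0
  eng <- psmcea:::prepare_arm(cfg$arms$pembro_chemo, cfg, "pembro_chemo")
  a <- psmcea:::evaluate_arm(eng, pars)
  expect_equal(a$qaly, 0.706 * 10 * 21 / 365.25, tolerance = 1e-9)
})

test_that("zeroed unit costs produce zero total cost", {
  cfg <- load_cfg("whole")
  pars <- baseline_pars(cfg)
  pars$costs[] <- 0
  pars$ae_costs[] <- 0
  for (eng in psmcea:::prepare_engines(cfg)) {
    a <- psmcea:::evaluate_arm(eng, pars)
    expect_equal(a$cost, 0)
    expect_equal(unname(a$ledger), rep(0, length(a$ledger)))
  }
})

test_that("expected adverse-event costs match the hand-summed profiles", {
  cfg <- load_cfg("whole")
  eng <- psmcea:::prepare_engines(cfg)
  pars <- baseline_pars(cfg)
  a1 <- psmcea:::evaluate_arm(eng$pembro_chemo, pars)
  a0 <- psmcea:::evaluate_arm(eng$chemo, pars)
  expect_equal(unname(a1$ledger["adverse_events"]), 549.32, tolerance = 1e-5)
  expect_equal(unname(a0$ledger["adverse_events"]), 281.78, tolerance = 1e-4)
})

test_that("undiscounted life-years match quadrature of the OS curve", {
  tm <- tbl_models()
  cfg <- load_cfg("whole")
  pars <- baseline_pars(cfg)
  pars$discount_rate <- 0
  eng <- psmcea:::prepare_arm(cfg$arms$chemo, cfg, "chemo")
  a <- psmcea:::evaluate_arm(eng, pars)
  auc <- stats::integrate(function(t) psurv(tm$os_chemo_whole, t), 0,
                          eng$K, rel.tol = 1e-10)$value
  cyc_y <- 21 / 365.25
  expect_lt(abs(a$ly - auc * cyc_y), cyc_y / 2)  # within half a cycle
})
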