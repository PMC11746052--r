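#' Cohort trace of the three-state partitioned-survival model
#'
#' Builds the progression-free / progressed / dead occupancy trace on the
#' cycle grid.  Occupancy is read directly off the two survival curves at
#' each cycle boundary: `pfs(t) = min(S_PFS(t), S_OS(t))` (clamped so the
#' progressed-disease compartment can never be negative),
#' `pd(t) = S_OS(t) - pfs(t)`, `dead(t) = 1 - S_OS(t)`.
#'
#' The survival models may be parameterized on either time grid: with
#' `time_unit = "cycles"` the curves are evaluated at the cycle index
#' itself (one unit = one model cycle); with `"months"` at the boundary
#' time in months (1 month = 30.4375 days).
#'
#' @param os_model,pfs_model [parsurv()] models.
#' @param horizon_years model horizon (default 10 years).
#' @param cycle_days cycle length in days (default 21, the treatment
#'   cadence).
#' @param time_unit `"cycles"` or `"months"`: grid on which the survival
#'   scales are interpreted.
#' @return data.frame of class `"psm_trace"` with one row per cycle
#'   boundary: `cycle`, `time_months`, `time_years`, `pfs`, `pd`, `dead`,
#'   and `deaths` (incident deaths during the cycle ending at the row's
#'   boundary).
#' @export
build_trace <- function(os_model, pfs_model, horizon_years = 10,
                        cycle_days = 21, time_unit = c("cycles", "months")) {
  time_unit <- match.arg(time_unit)
  if (horizon_years <= 0 || cycle_days <= 0)
    stop("horizon and cycle length must be positive", call. = FALSE)
  K <- ceiling(horizon_years * 365.25 / cycle_days)
  k <- 0:K
  t_model <- if (time_unit == "cycles") k else k * cycle_days / 30.4375
  s_os <- psurv(os_model, t_model)
  s_pfs <- psurv(pfs_model, t_model)
  pfs <- pmin(s_pfs, s_os)
  pd <- s_os - pfs
  dead <- 1 - s_os
  out <- data.frame(cycle = k,
                    time_months = k * cycle_days / 30.4375,
                    time_years = k * cycle_days / 365.25,
                    pfs = pfs, pd = pd, dead = dead,
                    deaths = c(0, diff(dead)))
  attr(out, "cycle_days") <- cycle_days
  attr(out, "time_unit") <- time_unit
  class(out) <- c("psm_trace", "data.frame")
  out
}

#' Discount factor
#'
#' `(1 + rate)^(-t)` for time `t` in years.  With `method = "annual"` the
#' exponent is the number of completed years `floor(t)` (stage-based
#' discounting in annual steps); with `"continuous"` it is `t` itself.
#'
#' @param t_years time in years (vectorized).
#' @param annual_rate discount rate per year (default 0.05).
#' @param method `"annual"` or `"continuous"`.
#' @return discount factors in (0, 1].
#' @export
discount_factor <- function(t_years, annual_rate = 0.05,
                            method = c("annual", "continuous")) {
  method <- match.arg(method)
  if (annual_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  if (any(t_years < 0)) stop("t must be >= 0", call. = FALSE)
  expo <- if (method == "annual") floor(t_years + 1e-9) else t_years
  (1 + annual_rate)^(-expo)
}

# fractional per-cycle weight for a capped schedule: full weight for cycles
# 1..floor(cap), pro-rated weight for the partial last cycle
cap_weights <- function(cap, K) {
  w <- numeric(K)
  if (cap <= 0) return(w)
  fl <- min(floor(cap), K)
  w[seq_len(fl)] <- 1
  if (fl < K && cap > fl) w[fl + 1] <- cap - fl
  w
}

# CT imaging schedule: every 2 cycles (6 weeks) for the first three scans,
# then every 4 cycles (12 weeks)
ct_schedule <- function(K) {
  cyc <- c(2, 4, 6, seq(10, K, by = 4))
  cyc[cyc <= K]
}

#' Precompute the accrual structure of one strategy arm
#'
#' Internal workhorse behind [run_cea()], [owsa()] and [psa()].  From the
#' occupancy trace and the arm's schedules it builds, per unit-price item,
#' the per-boundary quantity vector (occupancy-weighted doses, tests,
#' scans, incident deaths ...), so that total discounted cost is a linear
#' function `sum_j price_j * (Q_j . df)` of the unit prices for any
#' discount vector `df`.  QALY and life-year accrual use half-cycle
#' trapezoid weights (or start-of-cycle weights when `half_cycle = "none"`).
#'
#' @param arm arm specification (see [study_config()]).
#' @param config study configuration.
#' @param id arm identifier (its name in `config$arms`).
#' @return an opaque list consumed by [evaluate_arm()].
#' @keywords internal
prepare_arm <- function(arm, config, id = arm$label) {
  tr <- build_trace(parsurv_from_spec(arm$os), parsurv_from_spec(arm$pfs),
                    horizon_years = config$horizon_years,
                    cycle_days = config$cycle_days,
                    time_unit = config$time_unit)
  K <- nrow(tr) - 1
  cyc_y <- config$cycle_days / 365.25
  start <- seq_len(K)          # boundary position of cycle k's start (k)
  Q <- list()                  # per-item quantity vectors on boundaries 0..K
  add_q <- function(item, positions, quantity) {
    v <- Q[[item]]
    if (is.null(v)) v <- numeric(K + 1)
    v[positions] <- v[positions] + quantity
    Q[[item]] <<- v
  }
  # chemotherapy backbone: drug + administration on chemo-containing cycles
  wch <- cap_weights(arm$chemo_cycles, K)
  for (d in arm$chemo_drugs) add_q(d, start, tr$pfs[start] * wch)
  add_q("admin_premedication", start, tr$pfs[start] * wch)
  add_q("admin_infusion", start, tr$pfs[start] * wch)
  # antibody: acquisition cost only over the paid cycles (assistance
  # program); administration continues over all antibody cycles
  if (!is.null(arm$antibody_drug)) {
    wab <- cap_weights(arm$antibody_cycles, K)
    wpaid <- cap_weights(min(arm$antibody_paid_cycles, arm$antibody_cycles), K)
    add_q(arm$antibody_drug, start, tr$pfs[start] * wpaid)
    wonly <- pmax(wab - wch, 0)  # antibody-only cycles
    add_q("admin_premedication_secondary", start, tr$pfs[start] * wonly)
    add_q("admin_infusion", start, tr$pfs[start] * wonly)
  }
  # monitoring while alive
  alive <- tr$pfs + tr$pd
  add_q("laboratory", start, alive[start])
  add_q("ct_scan", ct_schedule(K), alive[ct_schedule(K)])
  # subsequent treatment in the progressed state
  sub <- arm$subsequent
  if (!is.null(sub) && length(sub$drugs)) {
    if (identical(sub$mode, "one_time")) {
      entrants <- pmax(0, diff(tr$pd))
      for (d in sub$drugs) add_q(d, 1 + seq_len(K), entrants)
    } else {
      wsub <- cap_weights(sub$cap_cycles, K)
      for (d in sub$drugs) add_q(d, start, tr$pd[start] * wsub)
    }
  }
  # end of life, charged at the boundary ending the cycle of death
  add_q("end_of_life", 1 + seq_len(K), diff(tr$dead))
  # QALY / LY weights (per-boundary, in years)
  w <- if (identical(config$half_cycle, "none"))
    c(rep(cyc_y, K), 0)
  else  # trapezoid half-cycle correction
    cyc_y * c(0.5, rep(1, K - 1), 0.5)
  list(id = id, label = arm$label, trace = tr, K = K, cyc_y = cyc_y,
       t_years = tr$time_years, Q = Q, w = w,
       pfs = tr$pfs, pd = tr$pd, alive = alive,
       sub_items = if (is.null(sub)) character(0) else as.character(sub$drugs),
       ae_incidence = unlist(arm$ae_incidence))
}

#' Evaluate one prepared arm at a parameter set
#'
#' @param eng result of [prepare_arm()].
#' @param pars parameter set as produced by [baseline_pars()] (unit costs,
#'   utilities, adverse-event inputs, discount settings).
#' @return list with `cost`, `qaly`, `ly`, and a cost `ledger` by category.
#' @keywords internal
evaluate_arm <- function(eng, pars) {
  df <- discount_factor(eng$t_years, pars$discount_rate,
                        pars$discount_method)
  items <- names(eng$Q)
  disc_q <- vapply(eng$Q, function(v) sum(v * df), numeric(1))
  prices <- pars$costs[items]
  if (anyNA(prices))
    stop("no unit cost for item(s): ",
         paste(items[is.na(prices)], collapse = ", "), call. = FALSE)
  item_cost <- disc_q * prices
  names(item_cost) <- items
  inc <- pars$ae_incidence[[eng$id]] %||% eng$ae_incidence
  ae_cost <- sum(inc * pars$ae_costs[names(inc)]) * df[1]
  admin_items <- c("admin_premedication", "admin_infusion",
                   "admin_premedication_secondary")
  drug_items <- setdiff(items, c(admin_items, "laboratory", "ct_scan",
                                 "end_of_life", eng$sub_items))
  ledger <- c(
    primary_treatment = sum(item_cost[drug_items]),
    subsequent_treatment = sum(item_cost[intersect(items, eng$sub_items)]),
    administration = sum(item_cost[intersect(items, admin_items)]),
    laboratory = sum(item_cost[intersect(items, "laboratory")]),
    imaging = sum(item_cost[intersect(items, "ct_scan")]),
    end_of_life = sum(item_cost[intersect(items, "end_of_life")]),
    adverse_events = ae_cost)
  qt_pfs <- sum(eng$w * eng$pfs * df)
  qt_pd <- sum(eng$w * eng$pd * df)
  ae_dec <- sum(inc * pars$ae_disutilities[names(inc)]) * eng$cyc_y * df[1]
  list(cost = sum(ledger),
       qaly = pars$utility_pfs * qt_pfs + pars$utility_pd * qt_pd - ae_dec,
       ly = sum(eng$w * eng$alive * df),
       ledger = ledger)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
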