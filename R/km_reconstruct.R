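#' Digitized Kaplan-Meier curve
#'
#' Bundles the step coordinates extracted from a published Kaplan-Meier plot
#' with its number-at-risk table, the two ingredients needed to reconstruct
#' pseudo individual-patient data.
#'
#' Small digitization noise (survival increases of at most `1e-3` between
#' consecutive steps) is clamped to monotone; larger violations are errors.
#'
#' @param points data.frame with columns `time`, `survival`: the step
#'   coordinates, survival in `[0, 1]` starting at 1.
#' @param risk_table data.frame with columns `time`, `n_at_risk`:
#'   non-increasing positive counts at at least two anchor times.
#' @param total_events optional total number of events, if reported.
#' @return an object of class `"digitized_km"`.
#' @export
digitized_km <- function(points, risk_table, total_events = NULL) {
  stopifnot(is.data.frame(points), all(c("time", "survival") %in% names(points)),
            is.data.frame(risk_table),
            all(c("time", "n_at_risk") %in% names(risk_table)))
  points <- points[order(points$time), c("time", "survival")]
  risk_table <- risk_table[order(risk_table$time), c("time", "n_at_risk")]
  if (nrow(risk_table) < 2)
    stop("risk table needs at least two anchor times", call. = FALSE)
  if (any(diff(risk_table$n_at_risk) > 0))
    stop("number at risk must be non-increasing", call. = FALSE)
  if (any(risk_table$n_at_risk < 0) ||
      any(risk_table$n_at_risk != round(risk_table$n_at_risk)))
    stop("number at risk must be non-negative integers", call. = FALSE)
  if (any(points$survival < 0 | points$survival > 1))
    stop("survival must lie in [0, 1]", call. = FALSE)
  # ensure the curve starts at (0, 1)
  if (points$time[1] > 0 || points$survival[1] < 1)
    points <- rbind(data.frame(time = 0, survival = 1), points)
  incr <- diff(points$survival)
  if (any(incr > 1e-3))
    stop("survival increases beyond digitization tolerance (1e-3)",
         call. = FALSE)
  points$survival <- cummin(points$survival)  # clamp sub-tolerance noise
  structure(list(points = points, risk_table = risk_table,
                 total_events = total_events),
            class = "digitized_km")
}

#' @export
print.digitized_km <- function(x, ...) {
  cat("Digitized Kaplan-Meier curve:", nrow(x$points), "steps,",
      nrow(x$risk_table), "risk-table anchors\n")
  cat(sprintf("  initial n at risk: %d; final survival %.3f at t = %.3g\n",
              x$risk_table$n_at_risk[1], min(x$points$survival),
              max(x$points$time)))
  invisible(x)
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Implements the standard reconstruction algorithm for published
#' Kaplan-Meier curves: within each interval between number-at-risk
#' anchors, censoring times are assumed uniformly distributed and their
#' count is adjusted iteratively until the implied number at risk at the
#' next anchor matches the published value; event counts at each digitized
#' step are chosen so the reconstructed product-limit estimate tracks the
#' digitized survival.  Beyond the last anchor, events are allocated from
#' the remaining steps without interior censoring and survivors are
#' censored at the last coordinate.  When the total event count is
#' supplied, the tail allocation is reconciled against it.  The procedure
#' is deterministic.
#'
#' @param km a [digitized_km()] object.
#' @return data.frame of class `"pseudo_ipd"` with columns `time` and
#'   `event` (1 = event, 0 = censored).
#' @references Guyot-style secondary-data reconstruction from published
#'   survival curves and at-risk tables.
#' @export
reconstruct_ipd <- function(km) {
  stopifnot(inherits(km, "digitized_km"))
  pts <- km$points
  rt <- km$risk_table
  t_ev <- numeric(0); t_cens <- numeric(0)
  n_cur <- rt$n_at_risk[1]
  S_run <- 1
  for (i in seq_len(nrow(rt) - 1)) {
    lo <- rt$time[i]; hi <- rt$time[i + 1]
    n_next <- rt$n_at_risk[i + 1]
    idx <- which(pts$time > lo & pts$time <= hi & pts$survival < 1)
    step_t <- pts$time[idx]; step_s <- pts$survival[idx]
    c_hat <- 0
    for (iter in 1:100) {
      cens_t <- if (c_hat > 0) lo + (seq_len(c_hat) - 0.5) / c_hat * (hi - lo)
                else numeric(0)
      n <- n_cur; S <- S_run
      d_tot <- 0; ev_t <- numeric(0)
      for (j in seq_along(step_t)) {
        n_j <- n - sum(cens_t < step_t[j]) - d_tot
        if (n_j <= 0) break
        d_j <- round(n_j * (1 - step_s[j] / S))
        d_j <- max(0, min(d_j, n_j))
        if (d_j > 0) {
          S <- S * (1 - d_j / n_j)
          ev_t <- c(ev_t, rep(step_t[j], d_j))
          d_tot <- d_tot + d_j
        }
      }
      n_end <- n_cur - d_tot - c_hat
      gap <- n_end - n_next
      if (gap == 0) break
      c_new <- max(0, min(c_hat + gap, n_cur - d_tot))
      if (c_new == c_hat) break
      c_hat <- c_new
    }
    t_ev <- c(t_ev, ev_t)
    t_cens <- c(t_cens, cens_t)
    n_cur <- n_cur - d_tot - c_hat
    S_run <- S
    if (n_cur <= 0) break
  }
  # beyond the last anchor: events only, then administrative censoring
  lo <- rt$time[nrow(rt)]
  idx <- which(pts$time > lo & pts$survival < 1)
  for (j in idx) {
    if (n_cur <= 0) break
    d_j <- round(n_cur * (1 - pts$survival[j] / S_run))
    d_j <- max(0, min(d_j, n_cur))
    if (d_j > 0) {
      S_run <- S_run * (1 - d_j / n_cur)
      t_ev <- c(t_ev, rep(pts$time[j], d_j))
      n_cur <- n_cur - d_j
    }
  }
  if (!is.null(km$total_events)) {
    # reconcile the overall event count against the reported total by
    # trading tail censorings for events at the last coordinate (or back)
    deficit <- km$total_events - length(t_ev)
    if (deficit > 0 && n_cur > 0) {
      k <- min(deficit, n_cur)
      t_ev <- c(t_ev, rep(max(pts$time), k))
      n_cur <- n_cur - k
    } else if (deficit < 0) {
      drop <- order(t_ev, decreasing = TRUE)[seq_len(min(-deficit, length(t_ev)))]
      t_cens <- c(t_cens, t_ev[drop])
      t_ev <- t_ev[-drop]
    }
  }
  # survivors are censored at the end of follow-up (last coordinate or
  # last risk-table anchor, whichever is later)
  t_end <- max(max(pts$time), rt$time[nrow(rt)])
  if (n_cur > 0) t_cens <- c(t_cens, rep(t_end, n_cur))
  out <- data.frame(time = c(t_ev, t_cens),
                    event = rep(c(1L, 0L), c(length(t_ev), length(t_cens))))
  out <- out[order(out$time, -out$event), ]
  rownames(out) <- NULL
  class(out) <- c("pseudo_ipd", "data.frame")
  out
}

#' Kaplan-Meier estimate of a pseudo-IPD set at given times
#'
#' Product-limit survival evaluated at `times`, used to verify that
#' reconstruction round-trips the digitized curve.
#'
#' @param ipd data.frame with `time`, `event`.
#' @param times evaluation times.
#' @return numeric vector of survival probabilities.
#' @export
km_at <- function(ipd, times) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  s <- c(1, fit$surv)
  tt <- c(0, fit$time)
  s[findInterval(times, tt)]
}

#' Read/write digitized curves and pseudo-IPD as CSV
#'
#' `read_km_csv()` assembles a [digitized_km()] from two plain CSV files:
#' the step coordinates (`time, survival`) and the risk table
#' (`time, n_at_risk`).  `write_ipd_csv()` writes a reconstructed data set
#' (`time, event`).
#'
#' @param points_file,risk_file CSV paths.
#' @param total_events optional known event count.
#' @param ipd a `pseudo_ipd` data.frame.
#' @param file output path.
#' @return `read_km_csv()` a `digitized_km`; `write_ipd_csv()` the path,
#'   invisibly.
#' @export
read_km_csv <- function(points_file, risk_file, total_events = NULL) {
  digitized_km(utils::read.csv(points_file), utils::read.csv(risk_file),
               total_events = total_events)
}

#' @rdname read_km_csv
#' @export
write_ipd_csv <- function(ipd, file) {
  utils::write.csv(as.data.frame(ipd)[, c("time", "event")], file,
                   row.names = FALSE)
  invisible(file)
}
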