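#' Synthetic two-endpoint trial generator
#'
#' `trial_scenario()` describes one simulated arm pair: overall-survival
#' (OS) and progression-free-survival (PFS) generating models per arm,
#' sample size, and a censoring mechanism (administrative cutoff plus a
#' uniform-dropout fraction).  `simulate_trial()` draws coupled subject
#' times: OS is drawn from its marginal and the latent progression time
#' from the PFS model, with observed PFS = min(progression, OS), so
#' PFS <= OS holds surely for every subject (the same ordering the
#' partitioned-survival engine enforces).  The marginal distribution of the
#' simulated PFS therefore deviates slightly from the nominal PFS model;
#' the generator is a test harness for the reconstruction and fitting
#' stages, not an estimate of any trial.
#'
#' @param arms named list of arms, each a list with elements `os` and `pfs`
#'   ([parsurv()] models).
#' @param n_per_arm subjects per arm (>= 10).
#' @param cutoff administrative censoring time (same unit as the models);
#'   `Inf` disables it.
#' @param dropout fraction of subjects with an additional uniform(0, cutoff)
#'   dropout time.
#' @param seed integer seed; the generator is reproducible given the seed.
#' @return `simulate_trial()`: named list per arm with `pseudo_ipd`
#'   data.frames `os` and `pfs` (columns `time`, `event`).
#' @export
trial_scenario <- function(arms, n_per_arm = 200, cutoff = Inf,
                           dropout = 0.1, seed = 1L) {
  stopifnot(n_per_arm >= 10, dropout >= 0, dropout <= 1, cutoff > 0)
  for (a in arms)
    stopifnot(inherits(a$os, "parsurv"), inherits(a$pfs, "parsurv"))
  structure(list(arms = arms, n_per_arm = n_per_arm, cutoff = cutoff,
                 dropout = dropout, seed = as.integer(seed)),
            class = "trial_scenario")
}

#' @rdname trial_scenario
#' @param scn a `trial_scenario`.
#' @export
simulate_trial <- function(scn) {
  stopifnot(inherits(scn, "trial_scenario"))
  set.seed(scn$seed)
  out <- lapply(scn$arms, function(arm) {
    n <- scn$n_per_arm
    os <- qsurv(arm$os, stats::runif(n))
    prog <- qsurv(arm$pfs, stats::runif(n))
    pfs <- pmin(prog, os)
    cens <- rep(scn$cutoff, n)
    drop <- stats::runif(n) < scn$dropout
    if (is.finite(scn$cutoff))
      cens[drop] <- stats::runif(sum(drop), 0, scn$cutoff)
    else
      cens[drop] <- Inf
    mk <- function(t) {
      obs <- pmin(t, cens)
      data.frame(time = obs, event = as.integer(t <= cens))
    }
    list(os = structure(mk(os), class = c("pseudo_ipd", "data.frame")),
         pfs = structure(mk(pfs), class = c("pseudo_ipd", "data.frame")))
  })
  out
}

#' Emulate curve digitization of individual-patient data
#'
#' Computes the Kaplan-Meier product-limit curve of the data, optionally
#' rounds the survival coordinates (mimicking plot-extraction error), and
#' tabulates the number at risk on a regular anchor grid -- producing the
#' same `digitized_km` structure one would obtain from a published figure.
#'
#' @param ipd data.frame with `time`, `event`.
#' @param anchor_spacing spacing of the number-at-risk anchors, in the time
#'   unit of the data (published risk tables typically use ~3 months).
#' @param round_digits decimals kept in the survival coordinates
#'   (`NULL` keeps full precision).
#' @return a [digitized_km()] object.
#' @export
digitize_km <- function(ipd, anchor_spacing = 3, round_digits = 3) {
  stopifnot(nrow(ipd) > 0)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(ipd))
  pts <- data.frame(time = c(0, fit$time), survival = c(1, fit$surv))
  if (!is.null(round_digits))
    pts$survival <- round(pts$survival, round_digits)
  anchors <- seq(0, max(ipd$time) + anchor_spacing, by = anchor_spacing)
  n_at <- vapply(anchors, function(a) sum(ipd$time >= a), integer(1))
  keep <- which(n_at > 0 | anchors == 0)
  digitized_km(pts,
               data.frame(time = anchors[keep], n_at_risk = n_at[keep]),
               total_events = sum(ipd$event))
}
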