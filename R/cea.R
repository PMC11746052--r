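#' Incremental cost-effectiveness ratio
#'
#' `(c1 - c0) / (e1 - e0)` from unrounded arm totals, with sign-based
#' dominance classification: an intervention that is cheaper and more
#' effective is `dominant` (no ICER is reported); costlier and less
#' effective is `dominated`.  When the effect difference is below `1e-9`
#' QALYs in absolute value the ICER is flagged undefined.
#'
#' @param c1,c0 total costs of intervention and comparator (USD).
#' @param e1,e0 total effects (QALYs).
#' @return list with `icer` (numeric or `NA`) and `status` (one of
#'   `"icer"`, `"dominant"`, `"dominated"`, `"undefined"`).
#' @export
icer <- function(c1, c0, e1, e0) {
  dc <- c1 - c0
  de <- e1 - e0
  if (abs(de) < 1e-9)
    return(list(icer = NA_real_, status = "undefined"))
  if (de > 0 && dc < 0) return(list(icer = NA_real_, status = "dominant"))
  if (de < 0 && dc > 0) return(list(icer = NA_real_, status = "dominated"))
  list(icer = dc / de, status = "icer")
}

#' Incremental net health and monetary benefit
#'
#' `INHB = dE - dC / lambda` (QALYs) and `INMB = dE * lambda - dC` (USD)
#' at willingness-to-pay `lambda`; the two satisfy `INMB = INHB * lambda`
#' identically.
#'
#' @param dc incremental cost (USD).
#' @param de incremental effect (QALYs).
#' @param lambda willingness-to-pay threshold (USD/QALY), > 0.
#' @return named vector `c(INHB = , INMB = )`.
#' @export
net_benefit <- function(dc, de, lambda) {
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  c(INHB = de - dc / lambda, INMB = de * lambda - dc)
}

#' Run the full cost-effectiveness comparison
#'
#' Builds the partitioned-survival trace for both arms of a study
#' configuration, accrues discounted costs and QALYs, and computes the
#' incremental statistics at the configured willingness-to-pay threshold.
#' The first arm in the configuration is the intervention, the second the
#' comparator.
#'
#' @param config a [study_config()] object (or the result of
#'   [load_study_config()]).
#' @param pars parameter set; defaults to the configuration baseline.
#'   Supplying a modified set is how the sensitivity analyses re-run the
#'   model.
#' @param engines optional pre-computed arm engines (internal reuse).
#' @return object of class `"cea"` with per-arm totals, incrementals,
#'   ICER, INHB and INMB.  Methods: `print()`, `summary()`,
#'   `as.data.frame()`.
#' @examples
#' \donttest{
#' cfg <- load_study_config(example_config("whole"))
#' res <- run_cea(cfg)
#' print(res)
#' }
#' @export
run_cea <- function(config, pars = baseline_pars(config), engines = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(engines)) engines <- prepare_engines(config)
  res <- lapply(engines, evaluate_arm, pars = pars)
  c1 <- res[[1]]$cost; c0 <- res[[2]]$cost
  e1 <- res[[1]]$qaly; e0 <- res[[2]]$qaly
  ic <- icer(c1, c0, e1, e0)
  nb <- net_benefit(c1 - c0, e1 - e0, config$wtp)
  structure(list(population = config$population,
                 arms = stats::setNames(res, names(engines)),
                 cost = c(c1, c0), qaly = c(e1, e0),
                 ly = c(res[[1]]$ly, res[[2]]$ly),
                 dc = c1 - c0, de = e1 - e0,
                 icer = ic$icer, status = ic$status,
                 inhb = nb[["INHB"]], inmb = nb[["INMB"]],
                 wtp = config$wtp),
            class = "cea")
}

prepare_engines <- function(config) {
  ids <- names(config$arms)
  stats::setNames(lapply(ids, function(id)
    prepare_arm(config$arms[[id]], config, id)), ids)
}

#' @export
as.data.frame.cea <- function(x, ...) {
  data.frame(arm = names(x$arms),
             cost = x$cost, qaly = x$qaly,
             incremental_cost = c(x$dc, NA),
             incremental_qaly = c(x$de, NA),
             INHB = c(x$inhb, NA), INMB = c(x$inmb, NA),
             ICER = c(if (x$status == "icer") x$icer else NA, NA),
             status = c(x$status, ""))
}

#' @export
print.cea <- function(x, ...) {
  cat("Partitioned-survival cost-effectiveness analysis (",
      x$population, " population)\n", sep = "")
  cat(sprintf("  %-34s cost $%10.2f   QALYs %6.3f\n",
              names(x$arms), x$cost, x$qaly), sep = "")
  cat(sprintf("  incremental: dC $%.2f, dE %.4f QALYs\n", x$dc, x$de))
  if (x$status == "icer")
    cat(sprintf("  ICER  $%.2f/QALY  (WTP $%.2f)\n", x$icer, x$wtp))
  else
    cat("  ICER: ", x$status, "\n", sep = "")
  cat(sprintf("  INHB %.4f QALYs   INMB $%.2f\n", x$inhb, x$inmb))
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  cat("Cost ledgers by category (discounted USD):\n")
  led <- sapply(object$arms, function(a) a$ledger)
  print(round(led, 2))
  cat("\nDiscounted life-years:",
      sprintf("%.4f", object$ly), "\n\n")
  print(object)
  invisible(object)
}
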