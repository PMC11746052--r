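#' Study configuration
#'
#' A study configuration bundles everything one comparison needs: the two
#' strategy arms (survival models, drug schedules and caps, subsequent
#' treatment, adverse-event profile), global unit costs, utilities,
#' discounting, the willingness-to-pay threshold, and the sensitivity-
#' analysis ranges.  Three fully populated configurations ship with the
#' package (see [example_config()]): the whole trial population and the
#' non-epithelioid and epithelioid histology subgroups.
#'
#' `load_study_config()` reads a YAML file and validates it;
#' `study_config()` validates an equivalent R list.
#'
#' @param x a named list mirroring the YAML schema.
#' @param path path to a YAML configuration.
#' @return a validated object of class `"study_config"`.
#' @export
study_config <- function(x) {
  defaults <- list(discount_rate = 0.05, discount_method = "annual",
                   horizon_years = 10, cycle_days = 21,
                   half_cycle = "trapezoid", time_unit = "cycles",
                   wtp = 38042.49, seed = 1L,
                   psa = list(n_draws = 10000, sd_divisor = 3.92))
  for (nm in names(defaults))
    if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
  x$psa <- utils::modifyList(defaults$psa, x$psa %||% list())
  class(x) <- "study_config"
  validate_config(x)
  x
}

#' @rdname study_config
#' @export
load_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  study_config(yaml::read_yaml(path))
}

#' Path to a shipped study configuration
#'
#' @param population `"whole"`, `"non_epithelioid"` or `"epithelioid"`.
#' @return file path inside the installed package.
#' @export
example_config <- function(population = c("whole", "non_epithelioid",
                                          "epithelioid")) {
  population <- match.arg(population)
  system.file("extdata", paste0("config_", population, ".yaml"),
              package = "psmcea", mustWork = TRUE)
}

validate_config <- function(x) {
  problems <- character(0)
  need <- c("population", "arms", "costs", "utilities", "ae")
  miss <- need[!need %in% names(x)]
  if (length(miss)) stop("config missing field(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (length(x$arms) != 2 || is.null(names(x$arms)))
    problems <- c(problems, "arms: exactly two named arms are required")
  u <- x$utilities
  if (is.null(u$pfs) || is.null(u$pd) ||
      u$pfs < 0 || u$pfs > 1 || u$pd < 0 || u$pd > 1)
    problems <- c(problems, "utilities: pfs and pd must lie in [0, 1]")
  else if (u$pd > u$pfs)
    problems <- c(problems, "utilities: pd must not exceed pfs")
  if (any(unlist(x$costs) < 0)) problems <- c(problems, "costs: negative unit cost")
  if (any(unlist(x$ae$costs) < 0)) problems <- c(problems, "ae costs: negative")
  if (any(unlist(x$ae$disutilities) < 0 | unlist(x$ae$disutilities) > 1))
    problems <- c(problems, "ae disutilities: outside [0, 1]")
  if (x$wtp <= 0) problems <- c(problems, "wtp: must be positive")
  if (x$horizon_years <= 0 || x$cycle_days <= 0)
    problems <- c(problems, "horizon_years/cycle_days: must be positive")
  for (id in names(x$arms)) {
    arm <- x$arms[[id]]
    if (is.null(arm$os) || is.null(arm$pfs))
      { problems <- c(problems, sprintf("arm %s: os and pfs models required", id)); next }
    inc <- unlist(arm$ae_incidence)
    if (any(inc < 0 | inc > 1))
      problems <- c(problems, sprintf("arm %s: incidences outside [0, 1]", id))
    if (!is.null(arm$subsequent) && length(arm$subsequent$drugs) == 0)
      problems <- c(problems, sprintf("arm %s: subsequent rule without drugs", id))
  }
  if (length(problems))
    stop("invalid study configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  # plausibility: implied median OS in months
  for (id in names(x$arms)) {
    m <- parsurv_from_spec(x$arms[[id]]$os)
    med <- tryCatch(median_survival(m), error = function(e) NA_real_)
    med_months <- if (identical(x$time_unit, "cycles"))
      med * x$cycle_days / 30.4375 else med
    if (is.finite(med_months) && (med_months < 5 || med_months > 40))
      warning(sprintf(
        "arm '%s': implied median OS %.1f months is outside 5-40 months",
        id, med_months), call. = FALSE)
  }
  invisible(x)
}

# build a parsurv model from its config fragment (family + named params)
parsurv_from_spec <- function(spec) {
  if (inherits(spec, "parsurv")) return(spec)
  pars <- spec[setdiff(names(spec), "family")]
  do.call(parsurv, c(list(family = spec$family), pars))
}

#' Baseline parameter set of a configuration
#'
#' Collects the tunable inputs (unit costs, utilities, adverse-event costs,
#' disutilities and incidences, discount settings) into the flat structure
#' consumed by [run_cea()], [owsa()] and [psa()].
#'
#' @param config a [study_config()].
#' @return named list.
#' @export
baseline_pars <- function(config) {
  list(costs = unlist(config$costs),
       utility_pfs = config$utilities$pfs,
       utility_pd = config$utilities$pd,
       ae_costs = unlist(config$ae$costs),
       ae_disutilities = unlist(config$ae$disutilities),
       ae_incidence = lapply(config$arms, function(a) unlist(a$ae_incidence)),
       discount_rate = config$discount_rate,
       discount_method = config$discount_method)
}

#' Calibrate an unstated treatment duration against a cost total
#'
#' The source tables print per-arm cost totals but not the duration of
#' subsequent treatment in the progressed state, nor the number of
#' assistance-program paid antibody cycles.  This routine solves, by
#' monotone root finding over a continuous cycle count (the final cycle
#' pro-rated), for the duration at which the arm's total discounted cost
#' equals `target_cost`, all other inputs at baseline.
#'
#' @param config a [study_config()].
#' @param arm_id name of the arm in `config$arms`.
#' @param target_cost target total discounted cost (USD).
#' @param what which duration to solve for: the subsequent-treatment cap
#'   or the antibody paid-cycle count.
#' @return the calibrated duration, in cycles.
#' @export
calibrate_duration <- function(config, arm_id, target_cost,
                               what = c("subsequent_cap",
                                        "antibody_paid_cycles")) {
  what <- match.arg(what)
  pars <- baseline_pars(config)
  K <- ceiling(config$horizon_years * 365.25 / config$cycle_days)
  cost_at <- function(cap) {
    arm <- config$arms[[arm_id]]
    if (what == "subsequent_cap") arm$subsequent$cap_cycles <- cap
    else arm$antibody_paid_cycles <- cap
    evaluate_arm(prepare_arm(arm, config, arm_id), pars)$cost
  }
  lo <- cost_at(0); hi <- cost_at(K)
  if (target_cost <= lo) return(0)
  if (target_cost >= hi)
    stop("target cost unreachable: maximum attainable ", round(hi, 2),
         call. = FALSE)
  stats::uniroot(function(cap) cost_at(cap) - target_cost, c(0, K),
                 tol = 1e-7)$root
}

#' Run a configured study end to end and write result files
#'
#' Executes the requested stages on a configuration and writes plain-CSV
#' outputs plus a JSON run summary (carrying the configuration hash and
#' seeds, for provenance) into `out_dir`.
#'
#' * `base`: per-arm cohort traces and the incremental results table.
#' * `owsa`: tornado table (`tornado.csv`).
#' * `psa`: per-draw scatter (`psa_scatter.csv`) and acceptability curve
#'   (`ceac.csv`).
#'
#' @param config a [study_config()].
#' @param which stages to run.
#' @param out_dir output directory (created if needed).
#' @param n_draws Monte-Carlo draws for the PSA stage.
#' @param seed integer seed recorded in, and used by, the run.
#' @return invisibly, a list with the stage results.
#' @export
run_study <- function(config, which = c("base", "owsa", "psa"),
                      out_dir = ".", n_draws = config$psa$n_draws,
                      seed = config$seed) {
  stopifnot(inherits(config, "study_config"))
  which <- match.arg(which, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  meta <- list(config_hash = config_hash(config), seed = as.integer(seed),
               population = config$population,
               time_unit = config$time_unit,
               discount_method = config$discount_method,
               half_cycle = config$half_cycle,
               survival_parameters_in_psa = "fixed")
  if ("base" %in% which) {
    res <- run_cea(config)
    out$base <- res
    utils::write.csv(format_csv_num(as.data.frame(res)),
                     file.path(out_dir, "results.csv"), row.names = FALSE)
    engines <- prepare_engines(config)
    pars <- baseline_pars(config)
    for (id in names(engines)) {
      tr <- engines[[id]]$trace
      tr$disc_factor <- discount_factor(tr$time_years, config$discount_rate,
                                        config$discount_method)
      utils::write.csv(format_csv_num(tr),
                       file.path(out_dir, paste0("trace_", id, ".csv")),
                       row.names = FALSE)
    }
    meta$base <- list(icer = res$icer, inhb = res$inhb, inmb = res$inmb)
  }
  if ("owsa" %in% which) {
    tor <- owsa(config)
    out$owsa <- tor
    utils::write.csv(format_csv_num(as.data.frame(tor)),
                     file.path(out_dir, "tornado.csv"), row.names = FALSE)
  }
  if ("psa" %in% which) {
    ps <- psa(config, n = n_draws, seed = seed)
    out$psa <- ps
    utils::write.csv(format_csv_num(ps$draws),
                     file.path(out_dir, "psa_scatter.csv"), row.names = FALSE)
    utils::write.csv(format_csv_num(ps$ceac),
                     file.path(out_dir, "ceac.csv"), row.names = FALSE)
    meta$psa <- list(n_draws = n_draws,
                     p_ce_at_wtp = ceac_at(ps, config$wtp))
  }
  jsonlite::write_json(meta, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

format_csv_num <- function(df) {
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) signif(col, 10) else col)
  df
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  x <- unclass(config)
  yaml::write_yaml(x[order(names(x))], f)
  unname(tools::md5sum(f))
}
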