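#' Sensitivity-analysis parameter deck
#'
#' Enumerates every tunable scalar input of a configuration as one row:
#' unit costs, the two state utilities, adverse-event management costs,
#' disutilities, per-arm incidences, and the discount rate.  Ranges default
#' to +/-20% of baseline; entries of `config$ranges` (named `low`/`high`
#' pairs) override them, mirroring the handful of inputs whose published
#' ranges are not symmetric.  Distributions for probabilistic draws follow
#' the usual convention: gamma for costs, beta for quantities bounded in
#' \[0, 1\] (utilities, disutilities, incidences, discount rate).
#'
#' @param config a [study_config()].
#' @param include_discount whether the discount rate (published range
#'   0-8%, a methodological rather than value parameter) is part of the
#'   deck.  It is sampled in the probabilistic analysis but not varied in
#'   the one-way analysis, whose published convention is +/-20% variation
#'   of the value parameters.
#' @return data.frame with columns `name`, `baseline`, `low`, `high`,
#'   `dist`.
#' @export
param_deck <- function(config, include_discount = TRUE) {
  rows <- list()
  add <- function(name, baseline, dist) {
    rows[[name]] <<- data.frame(name = name, baseline = baseline,
                                low = 0.8 * baseline, high = 1.2 * baseline,
                                dist = dist)
  }
  for (nm in names(config$costs))
    add(paste0("cost_", nm), config$costs[[nm]], "gamma")
  add("utility_pfs", config$utilities$pfs, "beta")
  add("utility_pd", config$utilities$pd, "beta")
  for (nm in names(config$ae$costs))
    add(paste0("ae_cost_", nm), config$ae$costs[[nm]], "gamma")
  for (nm in names(config$ae$disutilities))
    add(paste0("disutility_", nm), config$ae$disutilities[[nm]], "beta")
  for (id in names(config$arms))
    for (nm in names(config$arms[[id]]$ae_incidence))
      add(paste0("incidence_", nm, "_", id),
          config$arms[[id]]$ae_incidence[[nm]], "beta")
  if (include_discount) add("discount_rate", config$discount_rate, "beta")
  deck <- do.call(rbind, rows)
  rownames(deck) <- NULL
  for (nm in names(config$ranges)) {
    i <- match(nm, deck$name)
    if (is.na(i)) {
      if (nm == "discount_rate" && !include_discount) next
      stop("range override for unknown parameter: ", nm, call. = FALSE)
    }
    deck$low[i] <- config$ranges[[nm]][[1]]
    deck$high[i] <- config$ranges[[nm]][[2]]
  }
  bad <- deck$low > deck$baseline | deck$high < deck$baseline
  if (any(bad)) stop("deck ranges must bracket the baseline: ",
                     paste(deck$name[bad], collapse = ", "), call. = FALSE)
  deck
}

# route one deck parameter into the flat parameter set
apply_param <- function(pars, name, value, arm_ids) {
  if (name == "utility_pfs") pars$utility_pfs <- value
  else if (name == "utility_pd") pars$utility_pd <- value
  else if (name == "discount_rate") pars$discount_rate <- value
  else if (startsWith(name, "ae_cost_"))
    pars$ae_costs[[sub("^ae_cost_", "", name)]] <- value
  else if (startsWith(name, "disutility_"))
    pars$ae_disutilities[[sub("^disutility_", "", name)]] <- value
  else if (startsWith(name, "cost_"))
    pars$costs[[sub("^cost_", "", name)]] <- value
  else if (startsWith(name, "incidence_")) {
    rest <- sub("^incidence_", "", name)
    hit <- FALSE
    for (id in arm_ids) {
      suf <- paste0("_", id)
      if (endsWith(rest, suf)) {
        ae <- substr(rest, 1, nchar(rest) - nchar(suf))
        pars$ae_incidence[[id]][[ae]] <- value
        hit <- TRUE
        break
      }
    }
    if (!hit) stop("cannot map incidence parameter: ", name, call. = FALSE)
  } else stop("unknown parameter: ", name, call. = FALSE)
  pars
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs the full deterministic model twice per parameter -- once at its
#' low and once at its high value, everything else at baseline -- and
#' records the two ICERs.  Rows are sorted by descending bar width
#' `|icer_high - icer_low|`.
#'
#' @param config a [study_config()].
#' @param deck parameter table, defaulting to [param_deck()].
#' @return data.frame of class `"cea_owsa"` with columns `name`,
#'   `icer_low`, `icer_high`, `width`, plus attribute `base_icer`.
#' @export
owsa <- function(config, deck = param_deck(config, include_discount = FALSE)) {
  engines <- prepare_engines(config)
  base_pars <- baseline_pars(config)
  ids <- names(config$arms)
  icer_at <- function(pars)
    run_cea(config, pars = pars, engines = engines)$icer
  rows <- lapply(seq_len(nrow(deck)), function(i) {
    lo <- icer_at(apply_param(base_pars, deck$name[i], deck$low[i], ids))
    hi <- icer_at(apply_param(base_pars, deck$name[i], deck$high[i], ids))
    data.frame(name = deck$name[i], icer_low = lo, icer_high = hi,
               width = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, out$name), ]  # name breaks width ties
  rownames(out) <- NULL
  attr(out, "base_icer") <- icer_at(base_pars)
  class(out) <- c("cea_owsa", "data.frame")
  out
}

#' @export
print.cea_owsa <- function(x, n = 10, ...) {
  cat(sprintf("One-way sensitivity analysis (base ICER $%.2f/QALY)\n",
              attr(x, "base_icer")))
  print.data.frame(utils::head(x, n), digits = 6)
  if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more parameters\n")
  invisible(x)
}

#' @export
plot.cea_owsa <- function(x, n = 10, ...) {
  d <- utils::head(x, n)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_icer")
  graphics::par(mar = c(4, 12, 2, 1))
  ylim <- c(0.5, nrow(d) + 0.5)
  xlim <- range(c(d$icer_low, d$icer_high, base))
  graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
                 xlab = "ICER (USD/QALY)", ylab = "",
                 main = "Tornado diagram")
  for (i in seq_len(nrow(d)))
    graphics::rect(pmin(d$icer_low[i], d$icer_high[i]), i - 0.35,
                   pmax(d$icer_low[i], d$icer_high[i]), i + 0.35,
                   col = "steelblue")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$name, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Moment-matched probabilistic draw for one parameter
#'
#' The published ranges are interpreted as 95% intervals:
#' `sd = (high - low) / (2 * 1.96)` (a `(high - low)/4` convention is
#' selectable via `sd_divisor`).  Gamma draws use
#' `shape = (m/sd)^2, rate = m/sd^2`; beta draws use method-of-moments on
#' `(m, sd)`, with the variance shrunk when it exceeds the maximum a
#' proper beta allows.  A degenerate range (or `dist = "fixed"`) returns
#' the baseline.
#'
#' @param baseline,low,high baseline value and range.
#' @param dist `"gamma"`, `"beta"` or `"fixed"`.
#' @param n number of draws.
#' @param sd_divisor divisor converting the range span into a standard
#'   deviation (default `2 * 1.96`).
#' @return numeric vector of `n` draws.
#' @export
sample_param <- function(baseline, low, high, dist, n = 1,
                         sd_divisor = 3.92) {
  sd <- (high - low) / sd_divisor
  if (dist == "fixed" || sd <= 0) return(rep(baseline, n))
  m <- baseline
  if (dist == "gamma") {
    if (m <= 0) return(rep(baseline, n))
    return(stats::rgamma(n, shape = (m / sd)^2, rate = m / sd^2))
  }
  if (dist == "beta") {
    v <- min(sd^2, 0.95 * m * (1 - m))
    if (v <= 0 || m <= 0 || m >= 1) return(rep(baseline, n))
    a <- m * (m * (1 - m) / v - 1)
    b <- (1 - m) * (m * (1 - m) / v - 1)
    return(stats::rbeta(n, pmax(a, 1e-6), pmax(b, 1e-6)))
  }
  stop("unknown distribution: ", dist, call. = FALSE)
}

#' Probabilistic sensitivity analysis
#'
#' Samples all deck parameters jointly and independently (survival-model
#' parameters are held fixed: no published ranges or distributions exist
#' for them, and the printed distribution assignments cover only cost and
#' utility inputs), re-evaluates both arms per draw, and summarizes the
#' incremental cloud as a cost-effectiveness acceptability curve over a
#' willingness-to-pay grid of $0-120,000/QALY in $1,000 steps plus the
#' exact configured threshold.
#'
#' @param config a [study_config()].
#' @param n number of Monte-Carlo draws (default 10,000).
#' @param seed integer seed; results are reproducible given the seed.
#' @param deck parameter table, defaulting to [param_deck()].
#' @return object of class `"cea_psa"`: `draws` (per-draw arm costs and
#'   QALYs and the incrementals), `ceac` (`lambda`, `probability`), the
#'   acceptance fraction at the configured threshold, and metadata.
#' @export
psa <- function(config, n = config$psa$n_draws, seed = config$seed,
                deck = param_deck(config)) {
  stopifnot(n >= 1)
  engines <- prepare_engines(config)
  base_pars <- baseline_pars(config)
  ids <- names(config$arms)
  set.seed(as.integer(seed))
  P <- vapply(seq_len(nrow(deck)), function(i)
    sample_param(deck$baseline[i], deck$low[i], deck$high[i], deck$dist[i],
                 n = n, sd_divisor = config$psa$sd_divisor),
    numeric(n))
  colnames(P) <- deck$name
  res <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("cost1", "qaly1", "cost0", "qaly0")))
  for (j in seq_len(n)) {
    pars <- base_pars
    for (i in seq_len(nrow(deck)))
      pars <- apply_param(pars, deck$name[i], P[j, i], ids)
    a1 <- evaluate_arm(engines[[1]], pars)
    a0 <- evaluate_arm(engines[[2]], pars)
    res[j, ] <- c(a1$cost, a1$qaly, a0$cost, a0$qaly)
  }
  draws <- as.data.frame(res)
  draws$dc <- draws$cost1 - draws$cost0
  draws$de <- draws$qaly1 - draws$qaly0
  lambda <- sort(unique(c(seq(0, 120000, by = 1000), config$wtp)))
  prob <- vapply(lambda, function(l) mean(draws$de * l - draws$dc > 0),
                 numeric(1))
  structure(list(draws = draws,
                 ceac = data.frame(lambda = lambda, probability = prob),
                 wtp = config$wtp, n = n, seed = as.integer(seed),
                 population = config$population,
                 survival_parameters = "fixed"),
            class = "cea_psa")
}

#' Acceptability probability at a threshold
#'
#' Fraction of PSA draws with positive incremental net monetary benefit at
#' willingness-to-pay `lambda`.
#'
#' @param x a [psa()] result.
#' @param lambda threshold (USD/QALY).
#' @return probability in \[0, 1\].
#' @export
ceac_at <- function(x, lambda) {
  stopifnot(inherits(x, "cea_psa"))
  mean(x$draws$de * lambda - x$draws$dc > 0)
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf(
    "Probabilistic sensitivity analysis (%s population): %d draws, seed %d\n",
    x$population, x$n, x$seed))
  cat(sprintf("  mean dC $%.2f, mean dE %.4f QALYs\n",
              mean(x$draws$dc), mean(x$draws$de)))
  cat(sprintf("  P(cost-effective at $%.2f/QALY) = %.2f%%\n",
              x$wtp, 100 * ceac_at(x, x$wtp)))
  invisible(x)
}

#' @export
plot.cea_psa <- function(x, which = c("ceac", "scatter"), ...) {
  which <- match.arg(which)
  if (which == "ceac") {
    graphics::plot(x$ceac$lambda, x$ceac$probability, type = "l",
                   ylim = c(0, 1), xlab = "Willingness to pay (USD/QALY)",
                   ylab = "P(cost-effective)",
                   main = "Cost-effectiveness acceptability curve")
    graphics::abline(v = x$wtp, lty = 2)
  } else {
    graphics::plot(x$draws$de, x$draws$dc, pch = 16, cex = 0.3,
                   col = grDevices::adjustcolor("steelblue", 0.4),
                   xlab = "Incremental QALYs", ylab = "Incremental cost (USD)",
                   main = "Cost-effectiveness plane")
    graphics::abline(a = 0, b = x$wtp, lty = 2)
    graphics::abline(h = 0, v = 0, col = "grey")
  }
  invisible(x)
}
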