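#' Maximum-likelihood fit of a parametric survival family
#'
#' Fits one of the eight [parsurv()] families to right-censored data by
#' maximizing the log-likelihood `sum(event) log f(t) + sum(censored) log
#' S(t)`.  Optimization is quasi-Newton (BFGS) on an unconstrained
#' transform of the parameters (log for positive parameters), with three
#' starting points: a moment-based initial, a median-based initial, and a
#' perturbation of the better of the two; the best converged local optimum
#' is returned.  The exponential family uses its closed-form estimator
#' `rate = events / sum(t)`.
#'
#' @param time observed times (event or censoring), all positive.
#' @param event event indicator (1 = event, 0 = censored).
#' @param family family name as in [parsurv()].
#' @param time_unit carried through to the fitted model.
#' @return object of class `"parsurv_fit"`: fitted [parsurv()] model,
#'   log-likelihood, parameter count `k`, sample size `n`, convergence flag.
#'   Methods: `coef()`, `logLik()` (hence `AIC()`/`BIC()`), `print()`.
#' @export
fit_parsurv <- function(time, event, family, time_unit = "months") {
  family <- match.arg(family, parsurv_families())
  stopifnot(length(time) == length(event), all(time > 0))
  event <- as.integer(event > 0)
  if (length(time) < 10) stop("need at least 10 records", call. = FALSE)
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)

  if (family == "exponential") {
    rate <- sum(event) / sum(time)
    mod <- parsurv("exponential", rate = rate, time_unit = time_unit)
    ll <- parsurv_loglik(mod, time, event)
    return(new_parsurv_fit(mod, ll, time, event, converged = TRUE))
  }

  trans <- par_transform(family)
  nll <- function(theta) {
    pars <- trans$from(theta)
    m <- try(suppressWarnings(
      parsurv_quick(family, pars, time_unit)), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    ll <- suppressWarnings(parsurv_loglik(m, time, event))
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- fit_starts(family, time, event)
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(trans$to(s), nll, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
             silent = TRUE)
    if (inherits(o, "try-error") || !is.finite(o$value)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || best$value >= 1e10)
    return(new_parsurv_fit(NULL, -Inf, time, event, converged = FALSE,
                           family = family))
  mod <- parsurv_quick(family, trans$from(best$par), time_unit)
  new_parsurv_fit(mod, -best$value, time, event,
                  converged = best$convergence == 0)
}

# construct without revalidation overhead but with the same invariants
parsurv_quick <- function(family, pars, time_unit) {
  names(pars) <- parsurv_parnames(family)
  validate_parsurv_params(family, pars)
  structure(list(family = family, params = pars, time_unit = time_unit),
            class = "parsurv")
}

#' Log-likelihood of a parametric model on right-censored data
#' @inheritParams fit_parsurv
#' @param model a [parsurv()] model.
#' @return scalar log-likelihood.
#' @export
parsurv_loglik <- function(model, time, event) {
  d <- dsurv(model, time)
  s <- psurv(model, time)
  sum(ifelse(event > 0, log(d), log(s)))
}

par_transform <- function(family) {
  pn <- parsurv_parnames(family)
  free <- pn %in% c("mu", "meanlog", "Q")
  list(to = function(p) { p[!free] <- log(p[!free]); p },
       from = function(th) { th[!free] <- exp(th[!free]); th })
}

fit_starts <- function(family, time, event) {
  te <- time[event > 0]
  m <- mean(te); s <- stats::sd(te); if (!is.finite(s) || s <= 0) s <- m / 2
  med <- stats::median(te)
  cv <- s / m
  base <- switch(family,
    weibull_aft = c(shape = max(0.5, 1 / cv), scale = m),
    weibull_ph  = { sh <- max(0.5, 1 / cv); c(shape = sh, rate = m^(-sh)) },
    gamma       = c(shape = max(0.2, 1 / cv^2), rate = max(1e-8, 1 / (m * cv^2))),
    gompertz    = c(shape = 0.1, rate = log(2) / med),
    loglogistic = c(shape = max(0.5, 1.5 / cv), scale = med),
    lognormal   = c(meanlog = log(med), sdlog = max(0.1, stats::sd(log(te)))),
    gengamma_prentice = c(mu = log(med), sigma = max(0.2, stats::sd(log(te))),
                          Q = 0.5))
  medb <- base
  alt <- switch(family,
    weibull_aft = c(shape = 1, scale = med / log(2)),
    weibull_ph  = c(shape = 1, rate = log(2) / med),
    gamma       = c(shape = 1, rate = log(2) / med),
    gompertz    = c(shape = 0.01, rate = log(2) / med),
    loglogistic = c(shape = 1.2, scale = med),
    lognormal   = c(meanlog = log(m) - 0.5 * log(1 + cv^2),
                    sdlog = sqrt(log(1 + cv^2))),
    gengamma_prentice = c(mu = log(med), sigma = max(0.2, stats::sd(log(te))),
                          Q = -0.5))
  pert <- base * stats::setNames(rep(1.25, length(base)), names(base))
  pert[names(pert) %in% c("mu", "meanlog", "Q")] <-
    base[names(base) %in% c("mu", "meanlog", "Q")] + 0.25
  list(base, alt, pert)
}

new_parsurv_fit <- function(model, loglik, time, event, converged,
                            family = model$family) {
  structure(list(model = model, family = family, loglik = loglik,
                 k = parsurv_npars(family), n = length(time),
                 nevent = sum(event > 0), converged = converged),
            class = "parsurv_fit")
}

#' @export
coef.parsurv_fit <- function(object, ...) object$model$params

#' @export
logLik.parsurv_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
print.parsurv_fit <- function(x, ...) {
  cat(sprintf("Parametric survival fit: %s (n = %d, events = %d)%s\n",
              x$family, x$n, x$nevent,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$model))
    cat(paste(sprintf("  %s = %.6g", names(x$model$params), x$model$params),
              collapse = "\n"), "\n")
  ic <- information_criteria(x$loglik, x$k, x$n)
  cat(sprintf("  logLik %.3f   AIC %.3f   BIC %.3f\n",
              x$loglik, ic[["AIC"]], ic[["BIC"]]))
  invisible(x)
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = 2k - 2 logLik`; `BIC = k log(n) - 2 logLik`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n number of records.
#' @return named vector `c(AIC = , BIC = )`.
#' @export
information_criteria <- function(loglik, k, n) {
  stopifnot(k >= 1, n >= 1)
  c(AIC = 2 * k - 2 * loglik, BIC = k * log(n) - 2 * loglik)
}

#' Fit all families and tabulate fit statistics
#'
#' Fits every family in `families` to the same data and assembles the
#' model-selection report (log-likelihood, parameter count, AIC, BIC per
#' family).  Families that fail to converge are flagged and excluded from
#' selection.
#'
#' @inheritParams fit_parsurv
#' @param families subset of [parsurv_families()].
#' @return object of class `"parsurv_fitset"`; `as.data.frame()` yields the
#'   report table, [select_best()] the winning family.
#' @export
fit_parsurv_set <- function(time, event,
                            families = parsurv_families(),
                            time_unit = "months") {
  fits <- lapply(families, function(f)
    tryCatch(fit_parsurv(time, event, f, time_unit),
             error = function(e) new_parsurv_fit(NULL, -Inf, time, event,
                                                 converged = FALSE, family = f)))
  names(fits) <- families
  structure(list(fits = fits, n = length(time)), class = "parsurv_fitset")
}

#' @export
as.data.frame.parsurv_fitset <- function(x, ...) {
  rows <- lapply(x$fits, function(f) {
    ic <- information_criteria(f$loglik, f$k, f$n)
    data.frame(family = f$family, loglik = f$loglik, k = f$k,
               AIC = ic[["AIC"]], BIC = ic[["BIC"]],
               converged = f$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.parsurv_fitset <- function(x, ...) {
  tab <- as.data.frame(x)
  tab$best <- ifelse(tab$family == select_best(x), "<-- best", "")
  print(tab, digits = 7)
  invisible(x)
}

#' Select the best-fitting family
#'
#' Lowest AIC among converged fits; ties broken by lower BIC, then by fewer
#' parameters.
#'
#' @param fitset a [fit_parsurv_set()] result.
#' @return family name.
#' @export
select_best <- function(fitset) {
  stopifnot(inherits(fitset, "parsurv_fitset"))
  tab <- as.data.frame(fitset)
  tab <- tab[tab$converged & is.finite(tab$AIC), ]
  if (nrow(tab) == 0) stop("no converged fits to select from", call. = FALSE)
  tab <- tab[order(tab$AIC, tab$BIC, tab$k), ]
  tab$family[1]
}
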