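#' Parametric survival models
#'
#' `parsurv()` constructs a parametric time-to-event model in one of the
#' eight families routinely used to extrapolate trial survival curves in
#' health-technology assessment.  The parameterizations follow the
#' conventions of standard survival software:
#'
#' * `exponential`: `rate`; S(t) = exp(-rate t)
#' * `weibull_aft`: `shape`, `scale`; S(t) = exp(-(t/scale)^shape)
#' * `weibull_ph`: `shape`, `rate`; S(t) = exp(-rate t^shape)
#' * `gamma`: `shape`, `rate`
#' * `gengamma_prentice`: `mu`, `sigma`, `Q` (Prentice parameterization;
#'   `Q` may be negative)
#' * `gompertz`: `shape`, `rate`; S(t) = exp(-(rate/shape)(e^(shape t) - 1))
#' * `loglogistic`: `shape`, `scale`; S(t) = 1 / (1 + (t/scale)^shape)
#' * `lognormal`: `meanlog`, `sdlog`
#'
#' @param family one of the family names above.
#' @param ... named parameters for the family (see list above).
#' @param time_unit unit in which `t` is measured; informational only.
#' @return an object of class `"parsurv"`.
#' @examples
#' m <- parsurv("loglogistic", shape = 1.686, scale = 17.896)
#' psurv(m, c(0, 12, 60))
#' median_survival(m)
#' @export
parsurv <- function(family, ..., time_unit = "months") {
  family <- match.arg(family, parsurv_families())
  params <- unlist(list(...))
  need <- parsurv_parnames(family)
  if (!all(need %in% names(params)))
    stop("family '", family, "' requires parameters: ",
         paste(need, collapse = ", "), call. = FALSE)
  params <- params[need]
  validate_parsurv_params(family, params)
  structure(list(family = family, params = params, time_unit = time_unit),
            class = "parsurv")
}

#' @export
print.parsurv <- function(x, ...) {
  cat("Parametric survival model:", x$family, "\n")
  cat(paste(sprintf("  %s = %.6g", names(x$params), x$params), collapse = "\n"),
      "\n")
  med <- tryCatch(median_survival(x), error = function(e) NA_real_)
  cat(sprintf("  median survival: %.4g %s\n", med, x$time_unit))
  invisible(x)
}

#' @rdname parsurv
#' @export
parsurv_families <- function() {
  c("exponential", "weibull_aft", "weibull_ph", "gamma",
    "gengamma_prentice", "gompertz", "loglogistic", "lognormal")
}

parsurv_parnames <- function(family) {
  switch(family,
    exponential       = "rate",
    weibull_aft       = c("shape", "scale"),
    weibull_ph        = c("shape", "rate"),
    gamma             = c("shape", "rate"),
    gengamma_prentice = c("mu", "sigma", "Q"),
    gompertz          = c("shape", "rate"),
    loglogistic       = c("shape", "scale"),
    lognormal         = c("meanlog", "sdlog"))
}

#' Number of free parameters of a family
#' @param family family name as in [parsurv()].
#' @return integer count (1 for exponential, 3 for generalized gamma, 2
#'   otherwise).
#' @export
parsurv_npars <- function(family) {
  length(parsurv_parnames(match.arg(family, parsurv_families())))
}

validate_parsurv_params <- function(family, params) {
  if (any(!is.finite(params)))
    stop("non-finite parameter for family '", family, "'", call. = FALSE)
  # mu, meanlog and Q are unrestricted reals; everything else must be > 0
  free <- c("mu", "meanlog", "Q")
  pos <- params[setdiff(names(params), free)]
  if (any(pos <= 0))
    stop("parameter(s) ", paste(names(pos)[pos <= 0], collapse = ", "),
         " must be strictly positive for family '", family, "'",
         call. = FALSE)
  invisible(TRUE)
}

check_time <- function(t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  t
}

# dispatch table: p-, d- and q-functions per family.  Standard families go
# through stats; the three HTA-specific ones through flexsurv.
.ps_fun <- function(model, what = c("p", "d", "q")) {
  what <- match.arg(what)
  p <- as.list(model$params)
  switch(model$family,
    exponential = switch(what,
      p = function(t) stats::pexp(t, p$rate, lower.tail = FALSE),
      d = function(t) stats::dexp(t, p$rate),
      q = function(s) stats::qexp(s, p$rate, lower.tail = FALSE)),
    weibull_aft = switch(what,
      p = function(t) stats::pweibull(t, p$shape, p$scale, lower.tail = FALSE),
      d = function(t) stats::dweibull(t, p$shape, p$scale),
      q = function(s) stats::qweibull(s, p$shape, p$scale, lower.tail = FALSE)),
    weibull_ph = switch(what,  # flexsurv scale is the PH rate multiplier
      p = function(t) flexsurv::pweibullPH(t, p$shape, p$rate, lower.tail = FALSE),
      d = function(t) flexsurv::dweibullPH(t, p$shape, p$rate),
      q = function(s) flexsurv::qweibullPH(s, p$shape, p$rate, lower.tail = FALSE)),
    gamma = switch(what,
      p = function(t) stats::pgamma(t, p$shape, rate = p$rate, lower.tail = FALSE),
      d = function(t) stats::dgamma(t, p$shape, rate = p$rate),
      q = function(s) stats::qgamma(s, p$shape, rate = p$rate, lower.tail = FALSE)),
    gengamma_prentice = switch(what,
      p = function(t) flexsurv::pgengamma(t, p$mu, p$sigma, p$Q, lower.tail = FALSE),
      d = function(t) flexsurv::dgengamma(t, p$mu, p$sigma, p$Q),
      q = function(s) flexsurv::qgengamma(s, p$mu, p$sigma, p$Q, lower.tail = FALSE)),
    gompertz = switch(what,
      p = function(t) flexsurv::pgompertz(t, p$shape, p$rate, lower.tail = FALSE),
      d = function(t) flexsurv::dgompertz(t, p$shape, p$rate),
      q = function(s) flexsurv::qgompertz(s, p$shape, p$rate, lower.tail = FALSE)),
    loglogistic = switch(what,
      p = function(t) flexsurv::pllogis(t, p$shape, p$scale, lower.tail = FALSE),
      d = function(t) flexsurv::dllogis(t, p$shape, p$scale),
      q = function(s) flexsurv::qllogis(s, p$shape, p$scale, lower.tail = FALSE)),
    lognormal = switch(what,
      p = function(t) stats::plnorm(t, p$meanlog, p$sdlog, lower.tail = FALSE),
      d = function(t) stats::dlnorm(t, p$meanlog, p$sdlog),
      q = function(s) stats::qlnorm(s, p$meanlog, p$sdlog, lower.tail = FALSE)))
}

#' Survival, density, hazard, quantile and random generation
#'
#' `psurv()` evaluates the survival function S(t); `dsurv()` the density;
#' `hsurv()` the hazard; `qsurv()` the survival quantile (the time at which
#' S(t) equals `s`); `rsurv()` draws i.i.d. event times by inversion.
#'
#' @param model a [parsurv()] model.
#' @param t vector of non-negative times.
#' @param s vector of survival probabilities in (0, 1].
#' @param n number of draws.
#' @param seed optional integer seed for reproducible draws.
#' @return numeric vector.
#' @export
psurv <- function(model, t) {
  stopifnot(inherits(model, "parsurv"))
  check_time(t)
  pmin(pmax(.ps_fun(model, "p")(t), 0), 1)
}

#' @rdname psurv
#' @export
dsurv <- function(model, t) {
  stopifnot(inherits(model, "parsurv"))
  check_time(t)
  .ps_fun(model, "d")(t)
}

#' @rdname psurv
#' @export
hsurv <- function(model, t) dsurv(model, t) / psurv(model, t)

#' @rdname psurv
#' @export
qsurv <- function(model, s) {
  stopifnot(inherits(model, "parsurv"))
  if (any(s < 0 | s > 1)) stop("survival probabilities must lie in [0, 1]",
                               call. = FALSE)
  .ps_fun(model, "q")(s)
}

#' Median survival time
#'
#' Time at which the survival function crosses one half.  Closed forms are
#' used where the family admits one; otherwise the survival quantile is
#' found by bracketed root finding on [psurv()] (bracket `[1e-8, 2000]`,
#' expanded geometrically, relative tolerance `1e-8`).
#'
#' @inheritParams psurv
#' @param method `"closed"` (quantile function, default) or `"root"`
#'   (bisection on the survival function; used mainly as a cross-check).
#' @return time at which S(t) = 0.5.
#' @export
median_survival <- function(model, method = c("closed", "root")) {
  method <- match.arg(method)
  if (method == "closed") {
    p <- as.list(model$params)
    return(switch(model$family,
      exponential = log(2) / p$rate,
      weibull_aft = p$scale * log(2)^(1 / p$shape),
      loglogistic = p$scale,
      lognormal   = exp(p$meanlog),
      qsurv(model, 0.5)))
  }
  surv_root(model, 0.5)
}

# bracketed root of S(t) = s, independent of the quantile functions
surv_root <- function(model, s, lower = 1e-8, upper = 2000) {
  while (psurv(model, upper) > s && upper < 1e12) upper <- upper * 4
  stats::uniroot(function(t) psurv(model, t) - s, c(lower, upper),
                 tol = 1e-8 * max(1, upper))$root
}

#' @rdname psurv
#' @export
rsurv <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "parsurv"), n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  qsurv(model, stats::runif(n))
}
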