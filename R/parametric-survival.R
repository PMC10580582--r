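#' Parametric survival distributions for extrapolation
#'
#' Constructs a parametric survival-time distribution in one of the six
#' families used to extrapolate progression-free and overall survival beyond
#' trial follow-up. Time is measured in months throughout the package.
#'
#' Survival functions (all for `t >= 0`, `S(0) = 1`):
#' \describe{
#'   \item{exponential}{`S(t) = exp(-lambda t)`, `lambda > 0`.}
#'   \item{weibull_ph}{proportional-hazards Weibull, `S(t) = exp(-lambda t^gamma)`,
#'     `lambda, gamma > 0`. This is the "WeibullPH" parameterisation, not the
#'     accelerated-failure-time one used by [stats::pweibull].}
#'   \item{log_logistic}{`S(t) = 1 / (1 + (t/lambda)^gamma)`; `lambda` is the
#'     scale (and the median), `gamma > 0` the shape.}
#'   \item{log_normal}{`S(t) = 1 - Phi((log t - lambda)/gamma)`; `lambda` is the
#'     log-scale location (unrestricted), `gamma > 0` the log-scale SD.}
#'   \item{gompertz}{`S(t) = exp(-(lambda/gamma)(exp(gamma t) - 1))`,
#'     `lambda > 0`. For `|gamma| < 1e-8` the exponential limit is used.}
#'   \item{gamma}{`S(t) = 1 - P(gamma, lambda t)` with `P` the regularised
#'     lower incomplete gamma function (shape `gamma`, rate `lambda`).}
#' }
#'
#' @param family One of `"exponential"`, `"weibull_ph"`, `"log_logistic"`,
#'   `"log_normal"`, `"gompertz"`, `"gamma"` (partial matching allowed).
#' @param lambda Rate / scale / location parameter (see Details).
#' @param gamma Shape / dispersion parameter; must be omitted (or `NA`) for the
#'   exponential family and positive otherwise.
#' @return An object of class `parametric_survival`.
#' @examples
#' d <- parametric_survival("weibull_ph", 0.0241553, 1.1284343)
#' psurv(d, c(0, 12, 24))
#' median(d)
#' @seealso [psurv()], [qsurv()], [hsurv()], [fit_parametric()]
#' @export
parametric_survival <- function(family, lambda, gamma = NA_real_) {
  family <- match.arg(family, psm_families())
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  if (family == "exponential") {
    if (lambda <= 0) stop("exponential: 'lambda' must be positive", call. = FALSE)
    gamma <- NA_real_
  } else {
    if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
      stop(sprintf("%s: 'gamma' must be a positive number", family), call. = FALSE)
    if (family != "log_normal" && lambda <= 0)
      stop(sprintf("%s: 'lambda' must be positive", family), call. = FALSE)
  }
  structure(list(family = family, lambda = as.numeric(lambda),
                 gamma = as.numeric(gamma), time_unit = "months"),
            class = "parametric_survival")
}

#' The six supported survival families
#' @return Character vector of family names.
#' @export
psm_families <- function() {
  c("exponential", "weibull_ph", "log_logistic", "log_normal", "gompertz", "gamma")
}

#' @export
print.parametric_survival <- function(x, ...) {
  p <- if (x$family == "exponential") sprintf("lambda = %g", x$lambda)
       else sprintf("lambda = %g, gamma = %g", x$lambda, x$gamma)
  cat(sprintf("<parametric_survival> %s (%s); median %.3f months\n",
              x$family, p, median(x)))
  invisible(x)
}

#' Survival function
#'
#' Evaluates `S(t)` for a [parametric_survival()] distribution. Vectorised
#' over `t`.
#'
#' @param dist A `parametric_survival` object.
#' @param t Non-negative times in months.
#' @return Numeric vector of survival probabilities in `[0, 1]`.
#' @export
psurv <- function(dist, t) {
  stopifnot(inherits(dist, "parametric_survival"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  l <- dist$lambda; g <- dist$gamma
  switch(dist$family,
    exponential  = exp(-l * t),
    weibull_ph   = exp(-l * t^g),
    log_logistic = 1 / (1 + (t / l)^g),
    log_normal   = stats::plnorm(t, meanlog = l, sdlog = g, lower.tail = FALSE),
    gompertz     = if (abs(g) < 1e-8) exp(-l * t) else exp(-(l / g) * expm1(g * t)),
    gamma        = stats::pgamma(t, shape = g, rate = l, lower.tail = FALSE))
}

#' Hazard function
#'
#' @inheritParams psurv
#' @return Hazard `h(t) = f(t)/S(t)` (per month), vectorised over `t`.
#' @export
hsurv <- function(dist, t) {
  stopifnot(inherits(dist, "parametric_survival"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  l <- dist$lambda; g <- dist$gamma
  switch(dist$family,
    exponential  = rep_len(l, length(t)),
    weibull_ph   = l * g * t^(g - 1),
    log_logistic = (g / l) * (t / l)^(g - 1) / (1 + (t / l)^g),
    log_normal   = exp(stats::dlnorm(t, l, g, log = TRUE) -
                       stats::plnorm(t, l, g, lower.tail = FALSE, log.p = TRUE)),
    gompertz     = if (abs(g) < 1e-8) rep_len(l, length(t)) else l * exp(g * t),
    gamma        = exp(stats::dgamma(t, shape = g, rate = l, log = TRUE) -
                       stats::pgamma(t, shape = g, rate = l, lower.tail = FALSE,
                                     log.p = TRUE)))
}

#' Inverse survival function (quantile of the survival time)
#'
#' Returns the time `t` such that `S(t) = p`; used for inverse-transform
#' simulation and median computation. Closed forms exist for every family.
#'
#' @inheritParams psurv
#' @param p Survival probabilities in `(0, 1]`.
#' @export
qsurv <- function(dist, p) {
  stopifnot(inherits(dist, "parametric_survival"))
  if (any(p <= 0 | p > 1)) stop("'p' must be in (0, 1]", call. = FALSE)
  l <- dist$lambda; g <- dist$gamma
  switch(dist$family,
    exponential  = -log(p) / l,
    weibull_ph   = (-log(p) / l)^(1 / g),
    log_logistic = l * ((1 - p) / p)^(1 / g),
    log_normal   = stats::qlnorm(p, meanlog = l, sdlog = g, lower.tail = FALSE),
    gompertz     = if (abs(g) < 1e-8) -log(p) / l else log1p(-g * log(p) / l) / g,
    gamma        = stats::qgamma(p, shape = g, rate = l, lower.tail = FALSE))
}

#' Median survival time
#'
#' @param x A `parametric_survival` object.
#' @param ... Unused.
#' @return Median survival in months (`S(median) = 1/2`).
#' @export
median.parametric_survival <- function(x, ...) qsurv(x, 0.5)

#' Serialise / deserialise a distribution to its configuration form
#'
#' The run configuration stores each distribution as a plain list
#' `list(family =, lambda =, gamma =)`, exactly as tabulated in the model
#' parameter table.
#'
#' @param x A `parametric_survival` object or a plain list with `family`,
#'   `lambda` and optional `gamma` entries.
#' @return `as_parametric_survival` returns a `parametric_survival`;
#'   `unclass`ing the object gives the list form.
#' @export
as_parametric_survival <- function(x) {
  if (inherits(x, "parametric_survival")) return(x)
  stopifnot(is.list(x), !is.null(x$family), !is.null(x$lambda))
  parametric_survival(x$family, x$lambda, if (is.null(x$gamma)) NA_real_ else x$gamma)
}
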