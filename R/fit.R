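#' Fit a parametric survival family to right-censored data
#'
#' Maximises the right-censored log-likelihood
#' `sum_events log f(t) + sum_censored log S(t)` for one of the six supported
#' families. The exponential rate has the closed-form estimate
#' `events / total exposure`, which is used exactly; two-parameter families are
#' maximised numerically on the log-parameter scale from several
#' method-of-moments starting points, so the result is deterministic given the
#' data.
#'
#' @param time Non-negative follow-up times in months.
#' @param status Event indicator: 1 (or `TRUE`) = event, 0 = right-censored.
#' @param family One of [psm_families()].
#' @return An object of class `parsurv_fit` with components `dist`
#'   (the fitted [parametric_survival()]), `loglik`, `k` (free parameters),
#'   `n`, `n_events`, `aic`, `bic`.
#' @examples
#' set.seed(1)
#' d <- parametric_survival("weibull_ph", 0.03, 1.2)
#' t <- qsurv(d, runif(200))
#' fit <- fit_parametric(t, rep(1, 200), "weibull_ph")
#' coef(fit); AIC(fit)
#' @export
fit_parametric <- function(time, status, family) {
  family <- match.arg(family, psm_families())
  stopifnot(length(time) == length(status))
  time <- as.numeric(time); status <- as.integer(as.logical(status))
  if (any(!is.finite(time)) || any(time < 0))
    stop("'time' must be finite and non-negative", call. = FALSE)
  n <- length(time); d <- sum(status)
  if (d < 2L)
    stop("fitting requires at least 2 events (all-censored data cannot identify the distribution)",
         call. = FALSE)
  # log t appears in several densities; guard exact zeros from digitised grids
  time <- pmax(time, 1e-8)

  if (family == "exponential") {
    lambda <- d / sum(time)                      # closed-form MLE
    dist <- parametric_survival("exponential", lambda)
    ll <- d * log(lambda) - lambda * sum(time)
    return(new_parsurv_fit(dist, ll, 1L, n, d))
  }

  nll <- function(theta) {
    dist <- theta_to_dist(family, theta)
    ll <- sum(log_dens(dist, time[status == 1L])) +
          sum(log_surv(dist, time[status == 0L]))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  fits <- lapply(start_values(family, time, status), function(th) {
    out <- try(stats::optim(th, nll, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(out, "try-error")) return(NULL)
    # quasi-Newton polish from the simplex optimum
    ref <- try(stats::optim(out$par, nll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (!inherits(ref, "try-error") && ref$value <= out$value) ref else out
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop(sprintf("%s fit failed to converge from all starting values", family),
         call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (best$value >= 1e10)
    stop(sprintf("%s fit did not reach a finite likelihood (n = %d, events = %d)",
                 family, n, d), call. = FALSE)
  new_parsurv_fit(theta_to_dist(family, best$par), -best$value, 2L, n, d)
}

new_parsurv_fit <- function(dist, loglik, k, n, n_events) {
  structure(list(dist = dist, loglik = loglik, k = k, n = n, n_events = n_events,
                 aic = 2 * k - 2 * loglik, bic = k * log(n) - 2 * loglik),
            class = "parsurv_fit")
}

theta_to_dist <- function(family, theta) {
  if (family == "log_normal")
    parametric_survival(family, theta[1L], exp(theta[2L]))
  else
    parametric_survival(family, exp(theta[1L]), exp(theta[2L]))
}

log_surv <- function(dist, t) {
  if (!length(t)) return(numeric(0))
  l <- dist$lambda; g <- dist$gamma
  switch(dist$family,
    exponential  = -l * t,
    weibull_ph   = -l * t^g,
    log_logistic = -log1p((t / l)^g),
    log_normal   = stats::plnorm(t, l, g, lower.tail = FALSE, log.p = TRUE),
    gompertz     = if (abs(g) < 1e-8) -l * t else -(l / g) * expm1(g * t),
    gamma        = stats::pgamma(t, shape = g, rate = l, lower.tail = FALSE,
                                 log.p = TRUE))
}

log_dens <- function(dist, t) {
  if (!length(t)) return(numeric(0))
  l <- dist$lambda; g <- dist$gamma
  switch(dist$family,
    exponential  = log(l) - l * t,
    weibull_ph   = log(l) + log(g) + (g - 1) * log(t) - l * t^g,
    log_logistic = log(g) - log(l) + (g - 1) * (log(t) - log(l)) -
                   2 * log1p((t / l)^g),
    log_normal   = stats::dlnorm(t, l, g, log = TRUE),
    gompertz     = if (abs(g) < 1e-8) log(l) - l * t
                   else log(l) + g * t - (l / g) * expm1(g * t),
    gamma        = stats::dgamma(t, shape = g, rate = l, log = TRUE))
}

# Method-of-moments-flavoured starting values on the optimiser scale.
start_values <- function(family, time, status) {
  ev <- time[status == 1L]
  if (!length(ev)) ev <- time
  rate0 <- sum(status) / sum(time)              # exponential exposure rate
  m <- mean(ev); v <- stats::var(ev); if (!is.finite(v) || v <= 0) v <- m^2
  med <- stats::median(ev)
  switch(family,
    weibull_ph = list(c(log(rate0), 0), c(log(rate0), log(1.5)),
                      c(log(rate0), log(0.7))),
    log_logistic = list(c(log(med), log(1.5)), c(log(med), 0),
                        c(log(med), log(3))),
    log_normal = list(c(mean(log(ev)), log(stats::sd(log(ev)) + 1e-3)),
                      c(log(med), 0)),
    gompertz = list(c(log(rate0), log(0.05)), c(log(rate0), log(0.005)),
                    c(log(rate0 / 2), log(0.1))),
    gamma = list(c(log(m / v), log(m^2 / v)), c(log(rate0), 0)))
}

#' @export
print.parsurv_fit <- function(x, ...) {
  cat(sprintf("<parsurv_fit> %s: logLik %.3f (k = %d, n = %d, %d events); AIC %.2f, BIC %.2f\n",
              x$dist$family, x$loglik, x$k, x$n, x$n_events, x$aic, x$bic))
  print(x$dist)
  invisible(x)
}

#' @export
coef.parsurv_fit <- function(object, ...) {
  d <- object$dist
  if (d$family == "exponential") c(lambda = d$lambda)
  else c(lambda = d$lambda, gamma = d$gamma)
}

#' @export
logLik.parsurv_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Predicted survival probabilities from a fitted distribution
#' @param object A `parsurv_fit`.
#' @param times Times (months) at which to evaluate the fitted survival curve.
#' @param ... Unused.
#' @export
predict.parsurv_fit <- function(object, times, ...) psurv(object$dist, times)

#' Simulate survival times from a fitted distribution
#' @param object A `parsurv_fit`.
#' @param nsim Number of draws.
#' @param seed Optional seed (an integer) for reproducibility.
#' @param ... Unused.
#' @export
simulate.parsurv_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  qsurv(object$dist, stats::runif(nsim))
}

#' Fit all six families and rank them by information criteria
#'
#' Fits every supported family to the same right-censored data and ranks the
#' results by AIC, breaking ties by BIC and then family name; this is the
#' selection rule used to pick the extrapolation distribution. Families whose
#' fit fails are dropped from the ranking with a warning.
#'
#' @inheritParams fit_parametric
#' @param ipd Optionally, a data frame with columns `time` and `event` instead
#'   of `time`/`status` vectors.
#' @return An object of class `surv_model_selection`: a ranking table plus the
#'   individual `parsurv_fit` objects.
#' @export
select_distribution <- function(time, status, ipd = NULL) {
  if (!is.null(ipd)) { time <- ipd$time; status <- ipd$event }
  if (sum(status) < 2L)
    stop("model selection requires at least 2 events", call. = FALSE)
  fits <- list()
  for (fam in psm_families()) {
    f <- tryCatch(fit_parametric(time, status, fam), error = function(e) {
      warning(sprintf("family '%s' excluded from ranking: %s", fam,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (!length(fits)) stop("no family could be fitted", call. = FALSE)
  tab <- data.frame(
    family = names(fits),
    lambda = vapply(fits, function(f) f$dist$lambda, numeric(1)),
    gamma  = vapply(fits, function(f) f$dist$gamma, numeric(1)),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    k      = vapply(fits, `[[`, integer(1), "k"),
    aic    = vapply(fits, `[[`, numeric(1), "aic"),
    bic    = vapply(fits, `[[`, numeric(1), "bic"),
    row.names = NULL)
  ord <- order(tab$aic, tab$bic, tab$family)
  tab <- tab[ord, , drop = FALSE]; rownames(tab) <- NULL
  structure(list(table = tab, fits = fits[tab$family],
                 best = fits[[tab$family[1L]]]),
            class = "surv_model_selection")
}

#' @export
print.surv_model_selection <- function(x, digits = 4, ...) {
  cat("Parametric survival model selection (ranked by AIC; ties by BIC, family)\n")
  print(format(x$table, digits = digits), row.names = TRUE)
  invisible(x)
}
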