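#' Engine configuration for the partitioned survival model
#'
#' @param cycle_length Cycle length in months (the model uses monthly cycles).
#' @param horizon Number of cycles; 120 monthly cycles give the 10-year study
#'   period over which most patients with this disease have died.
#' @param discount_rate Annual discount rate for costs and outcomes (0-0.08).
#' @param wtp Willingness-to-pay threshold, USD per QALY (3x the 2021 Chinese
#'   per-capita GDP).
#' @param midpoint Evaluate state occupancy at cycle midpoints (half-cycle
#'   correction) rather than cycle starts.
#' @param background_mortality Optional constant per-month background mortality
#'   hazard applied multiplicatively to overall survival; `NULL` (off) in the
#'   base case.
#' @return Object of class `engine_config`.
#' @export
engine_config <- function(cycle_length = 1, horizon = 120, discount_rate = 0.05,
                          wtp = 33819, midpoint = TRUE,
                          background_mortality = NULL) {
  stopifnot(cycle_length > 0, horizon >= 1)
  if (discount_rate < 0 || discount_rate > 0.08)
    stop("'discount_rate' must lie in [0, 0.08]", call. = FALSE)
  structure(list(cycle_length = cycle_length, horizon = as.integer(horizon),
                 discount_rate = discount_rate, wtp = wtp,
                 midpoint = isTRUE(midpoint),
                 background_mortality = background_mortality),
            class = "engine_config")
}

#' Health-state utilities and adverse-event disutilities
#'
#' Utilities are per year of life; adverse-event (AE) disutilities are one-off
#' per-event decrements applied, weighted by per-arm incidence, in the first
#' model cycle only. The three AEs retained are those with materially
#' different incidence between the arms (asthenia, anemia, neutropenia).
#'
#' @param u_pfs,u_pd,u_death Utilities of the progression-free, progressed and
#'   dead states.
#' @param ae_disutility Named vector of per-event utility decrements.
#' @param ae_incidence List with per-arm (`NI`, `C`) incidence vectors aligned
#'   with `ae_disutility`.
#' @export
health_utilities <- function(u_pfs = 0.706, u_pd = 0.565, u_death = 0,
    ae_disutility = c(asthenia = 0.07, anemia = 0.073, neutropenia = 0.20),
    ae_incidence = list(NI = c(asthenia = 0, anemia = 0.0033, neutropenia = 0.0067),
                        C  = c(asthenia = 0.042, anemia = 0.1127, neutropenia = 0.1514))) {
  for (u in c(u_pfs, u_pd, u_death))
    if (u < 0 || u > 1) stop("utilities must lie in [0, 1]", call. = FALSE)
  if (any(ae_disutility < 0)) stop("disutilities must be >= 0", call. = FALSE)
  for (inc in ae_incidence)
    if (any(inc < 0 | inc > 1)) stop("incidences must lie in [0, 1]", call. = FALSE)
  structure(list(u_pfs = u_pfs, u_pd = u_pd, u_death = u_death,
                 ae_disutility = ae_disutility, ae_incidence = ae_incidence),
            class = "health_utilities")
}

#' A treatment arm of the partitioned survival model
#'
#' @param name `"NI"` (nivolumab + ipilimumab) or `"C"` (pemetrexed-platinum
#'   chemotherapy).
#' @param pfs,os [parametric_survival()] distributions for progression-free and
#'   overall survival.
#' @param population `"A"` (all randomized), `"E"` (epithelioid) or `"N"`
#'   (non-epithelioid histology).
#' @export
arm_model <- function(name = c("NI", "C"), pfs, os, population = c("A", "E", "N")) {
  structure(list(name = match.arg(name), pfs = as_parametric_survival(pfs),
                 os = as_parametric_survival(os),
                 population = match.arg(population)),
            class = "arm_model")
}

#' @export
print.arm_model <- function(x, ...) {
  cat(sprintf("<arm_model> %s (population %s)\n  PFS: ", x$name, x$population))
  print(x$pfs); cat("  OS:  "); print(x$os)
  invisible(x)
}

#' State occupancy of the three-state partitioned survival model
#'
#' All patients enter progression-free; occupancy is read directly off the
#' survival curves without transition probabilities:
#' progression-free `= min(PFS(t), OS(t))`, progressed `= max(OS - PFS, 0)`,
#' dead `= 1 - OS`. With a background mortality hazard `h`, `OS` is first
#' replaced by `OS(t) exp(-h t)` so the overall death hazard never falls below
#' `h`.
#'
#' @param arm An [arm_model()].
#' @param t Times in months (vectorised).
#' @param background_mortality Optional per-month hazard.
#' @return Matrix with columns `pfs`, `pd`, `dead`; rows sum to 1.
#' @export
occupancy <- function(arm, t, background_mortality = NULL) {
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  os <- psurv(arm$os, t)
  if (!is.null(background_mortality) && background_mortality > 0)
    os <- os * exp(-background_mortality * t)
  pfs <- pmin(psurv(arm$pfs, t), os)
  cbind(pfs = pfs, pd = pmax(os - pfs, 0), dead = 1 - os)
}

#' Run the cohort trace for one arm
#'
#' Evaluates occupancy at every cycle (midpoints when half-cycle correction is
#' on, else cycle starts), accrues discounted life years and QALYs at 1/12
#' year per monthly cycle, subtracts the adverse-event QALY loss
#' (incidence x decrement x 1/12, undiscounted) in cycle 1, and records the
#' fraction of the cohort newly progressing in each cycle (the progression-free
#' decrement; progression is taken to precede death within a cycle), which the
#' cost model consumes. Discounting is `df(t) = (1 + r)^(-t/12)` with `t` in
#' months.
#'
#' @param arm An [arm_model()].
#' @param cfg An [engine_config()].
#' @param util A [health_utilities()].
#' @return Object of class `state_trace`: per-cycle data frame with occupancy,
#'   new progressors, discount factor, discounted LY and QALY increments, and
#'   attributes `ly`, `qaly` (totals), `arm`, `cfg`.
#' @export
run_trace <- function(arm, cfg = engine_config(), util = health_utilities()) {
  stopifnot(inherits(arm, "arm_model"), inherits(cfg, "engine_config"))
  cyc <- seq_len(cfg$horizon)
  te <- (cyc - ifelse(cfg$midpoint, 0.5, 1)) * cfg$cycle_length
  occ <- occupancy(arm, te, cfg$background_mortality)
  df <- (1 + cfg$discount_rate)^(-te / 12)
  # progression-free decrements over cycle boundaries
  tb <- (0:cfg$horizon) * cfg$cycle_length
  osb <- psurv(arm$os, tb)
  if (!is.null(cfg$background_mortality) && cfg$background_mortality > 0)
    osb <- osb * exp(-cfg$background_mortality * tb)
  pfsb <- pmin(psurv(arm$pfs, tb), osb)
  new_prog <- pmax(-diff(pfsb), 0)
  yrs <- cfg$cycle_length / 12
  ly <- (occ[, "pfs"] + occ[, "pd"]) * yrs * df
  qaly <- (occ[, "pfs"] * util$u_pfs + occ[, "pd"] * util$u_pd) * yrs * df
  inc <- util$ae_incidence[[arm$name]]
  qaly[1L] <- qaly[1L] - sum(inc * util$ae_disutility) * yrs   # undiscounted
  out <- data.frame(cycle = cyc, time = te, occ_pfs = occ[, "pfs"],
                    occ_pd = occ[, "pd"], occ_dead = occ[, "dead"],
                    new_prog = new_prog, df = df, ly = ly, qaly = qaly,
                    cum_ly = cumsum(ly), cum_qaly = cumsum(qaly))
  structure(out, ly = sum(ly), qaly = sum(qaly), arm = arm, cfg = cfg,
            class = c("state_trace", "data.frame"))
}

#' @export
print.state_trace <- function(x, ...) {
  arm <- attr(x, "arm")
  cat(sprintf("<state_trace> arm %s, %d cycles: discounted LY %.4f, QALY %.4f\n",
              arm$name, nrow(x), attr(x, "ly"), attr(x, "qaly")))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental QALYs.
#' @return A list with `icer` (USD/QALY, `NA` unless `delta_qaly > 0`) and
#'   `status`: `"icer"`, `"dominant"` (cheaper and more effective),
#'   `"dominated"` (costlier and less effective), or `"undefined"`
#'   (`delta_qaly == 0`).
#' @export
icer <- function(delta_cost, delta_qaly) {
  status <- if (delta_qaly > 0 && delta_cost >= 0) "icer"
    else if (delta_qaly > 0) "dominant"
    else if (delta_qaly < 0 && delta_cost > 0) "dominated"
    else if (delta_qaly == 0) "undefined"
    else "icer"   # both negative: cost saved per QALY forgone
  list(icer = if (delta_qaly != 0) delta_cost / delta_qaly else NA_real_,
       status = status)
}
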