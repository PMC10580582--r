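#' Model patient characteristics
#'
#' Dosing inputs for body-weight, body-surface-area and Calvert (AUC) dose
#' rules, matching the trial's median patient.
#'
#' @param weight Body weight, kg.
#' @param bsa Body surface area, m^2.
#' @param crcl Creatinine clearance, mL/min (used as GFR in the Calvert
#'   formula).
#' @param age Age in years.
#' @export
patient <- function(weight = 65, bsa = 1.72, crcl = 60, age = 69) {
  stopifnot(weight > 0, bsa > 0, crcl > 0, age > 0)
  structure(list(weight = weight, bsa = bsa, crcl = crcl, age = age),
            class = "psm_patient")
}

#' Unit prices and fee schedule
#'
#' Drug prices are USD per mg (median provincial bid prices); the
#' administration fee is charged once per administration day ("IV, first
#' hour"); follow-up is an outpatient visit fee per monthly cycle; AE costs
#' are one-off management costs charged in the first cycle only, undiscounted.
#'
#' @param drugs Named vector of USD/mg prices.
#' @param admin_iv Administration fee per administration day, USD.
#' @param followup Outpatient follow-up cost per cycle, USD.
#' @param ae_cost Named per-event AE management costs, USD.
#' @export
price_list <- function(
    drugs = c(nivolumab = 15.96, ipilimumab = 77.96, pemetrexed = 0.88,
              cisplatin = 0.12, carboplatin = 0.09, vinorelbine = 1.52,
              gemcitabine = 0.07),
    admin_iv = 7.83, followup = 69.13,
    ae_cost = c(asthenia = 96.05, anemia = 500.78, neutropenia = 434.57)) {
  if (any(c(drugs, admin_iv, followup, ae_cost) < 0))
    stop("prices and costs must be non-negative", call. = FALSE)
  structure(list(drugs = drugs, admin_iv = admin_iv, followup = followup,
                 ae_cost = ae_cost), class = "price_list")
}

#' Second-line treatment mixture
#'
#' After progression, patients in the NI arm receive pemetrexed-platinum
#' chemotherapy; patients in the C arm receive, with probability `p_immuno`,
#' nivolumab with or without ipilimumab, and otherwise single-agent
#' vinorelbine or gemcitabine. All mixture probabilities default to 1/2 with
#' full 0-1 ranges.
#'
#' @param p_carbo Probability of carboplatin (vs cisplatin) as the platinum.
#' @param p_immuno Probability of second-line immunotherapy in the C arm.
#' @param p_nivo_mono Probability of nivolumab monotherapy (vs nivolumab +
#'   ipilimumab) within immunotherapy.
#' @param p_vinorelbine Probability of vinorelbine (vs gemcitabine) within
#'   chemotherapy.
#' @param durations Months of second-line therapy: pemetrexed-platinum in the
#'   NI arm, immunotherapy in the C arm, mono-chemotherapy in the C arm.
#' @export
second_line_mix <- function(p_carbo = 0.5, p_immuno = 0.5, p_nivo_mono = 0.5,
                            p_vinorelbine = 0.5,
                            durations = c(ni_chemo = 5, c_immuno = 3, c_chemo = 16)) {
  for (p in c(p_carbo, p_immuno, p_nivo_mono, p_vinorelbine))
    if (p < 0 || p > 1) stop("mixture probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(p_carbo = p_carbo, p_immuno = p_immuno,
                 p_nivo_mono = p_nivo_mono, p_vinorelbine = p_vinorelbine,
                 durations = durations), class = "second_line_mix")
}

#' A drug regimen
#'
#' @param drug Drug name (must match a [price_list()] entry).
#' @param dose Dose per administration in the unit of `dose_rule`: mg/kg,
#'   mg/m^2, target AUC (mg.min/mL), or mg.
#' @param dose_rule How the absolute dose is computed from patient
#'   characteristics.
#' @param interval_days Days between dosing days.
#' @param days_dosed Administration days per interval (d1 + d8 schedules use 2).
#' @param doses_per_month Optional override of the dosing frequency; defaults
#'   to `days_dosed * 30.4375 / interval_days` (continuous calendar-month
#'   accrual).
#' @export
regimen <- function(drug, dose, dose_rule = c("per_kg", "per_bsa", "auc_calvert", "flat"),
                    interval_days, days_dosed = 1, doses_per_month = NULL) {
  dose_rule <- match.arg(dose_rule)
  stopifnot(interval_days > 0, days_dosed >= 1, dose >= 0)
  structure(list(drug = drug, dose = dose, dose_rule = dose_rule,
                 interval_days = interval_days, days_dosed = days_dosed,
                 doses_per_month = doses_per_month), class = "psm_regimen")
}

doses_per_month <- function(reg) {
  if (!is.null(reg$doses_per_month)) reg$doses_per_month
  else reg$days_dosed * 30.4375 / reg$interval_days
}

#' Absolute dose per administration
#'
#' `per_kg`: dose x weight; `per_bsa`: dose x body surface area;
#' `auc_calvert`: Calvert formula, AUC x (GFR + 25) with creatinine clearance
#' standing in for GFR; `flat`: dose as given.
#'
#' @param reg A [regimen()].
#' @param pt A [patient()].
#' @return Dose in mg.
#' @export
dose_mg <- function(reg, pt) {
  stopifnot(inherits(reg, "psm_regimen"), inherits(pt, "psm_patient"))
  switch(reg$dose_rule,
    per_kg      = reg$dose * pt$weight,
    per_bsa     = reg$dose * pt$bsa,
    auc_calvert = reg$dose * (pt$crcl + 25),
    flat        = reg$dose)
}

#' Monthly drug-acquisition cost of a regimen
#'
#' Dose x unit price x dosing frequency, plus one administration fee per
#' administration day when `admin = TRUE`. For multi-drug combinations use
#' [combo_monthly_cost()], which charges the administration fee once per
#' visit day rather than once per drug.
#'
#' @inheritParams dose_mg
#' @param prices A [price_list()].
#' @param admin Include the per-administration-day fee.
#' @return USD per month.
#' @export
per_cycle_drug_cost <- function(reg, pt, prices, admin = TRUE) {
  if (!reg$drug %in% names(prices$drugs))
    stop(sprintf("unknown drug '%s' (no unit price)", reg$drug), call. = FALSE)
  dpm <- doses_per_month(reg)
  dose_mg(reg, pt) * prices$drugs[[reg$drug]] * dpm +
    if (admin) prices$admin_iv * dpm else 0
}

#' Monthly cost of a drug combination
#'
#' Sums the component drug costs and charges one administration fee per
#' administration day; drugs infused on the same visit share the fee, so the
#' fee rate is the maximum dosing frequency among the components.
#'
#' @param regs List of [regimen()]s given concurrently.
#' @inheritParams per_cycle_drug_cost
#' @export
combo_monthly_cost <- function(regs, pt, prices) {
  drug <- sum(vapply(regs, per_cycle_drug_cost, numeric(1),
                     pt = pt, prices = prices, admin = FALSE))
  drug + prices$admin_iv * max(vapply(regs, doses_per_month, numeric(1)))
}

#' Expected first-cycle adverse-event management cost
#'
#' @param arm `"NI"` or `"C"`.
#' @param prices A [price_list()].
#' @param util A [health_utilities()] carrying the per-arm AE incidences.
#' @return Expected USD, charged once in cycle 1, undiscounted.
#' @export
ae_first_cycle_cost <- function(arm, prices, util = health_utilities()) {
  inc <- util$ae_incidence[[arm]]
  sum(inc * prices$ae_cost[names(inc)])
}

# -- regimen sets -----------------------------------------------------------

# `dosing` maps schedule labels to doses-per-month overrides (possibly NULL).
sched_dpm <- function(dosing, key) if (is.null(dosing)) NULL else dosing[[key]]

first_line_components <- function(arm, mix, dosing = NULL) {
  if (arm == "NI") list(
    list(w = 1, regs = list(
      regimen("nivolumab", 3, "per_kg", 14, doses_per_month = sched_dpm(dosing, "q2w")),
      regimen("ipilimumab", 1, "per_kg", 42, doses_per_month = sched_dpm(dosing, "q6w")))))
  else list(
    list(w = 1 - mix$p_carbo, regs = list(
      regimen("pemetrexed", 500, "per_bsa", 21, doses_per_month = sched_dpm(dosing, "q3w")),
      regimen("cisplatin", 75, "per_bsa", 21, doses_per_month = sched_dpm(dosing, "q3w")))),
    list(w = mix$p_carbo, regs = list(
      regimen("pemetrexed", 500, "per_bsa", 21, doses_per_month = sched_dpm(dosing, "q3w")),
      regimen("carboplatin", 5, "auc_calvert", 21, doses_per_month = sched_dpm(dosing, "q3w")))))
}

second_line_components <- function(arm, mix, dosing = NULL) {
  q2w <- sched_dpm(dosing, "q2w"); q3w <- sched_dpm(dosing, "q3w")
  q6w <- sched_dpm(dosing, "q6w"); d1d8 <- sched_dpm(dosing, "d1d8")
  if (arm == "NI") {
    dur <- mix$durations[["ni_chemo"]]
    list(
      list(w = 1 - mix$p_carbo, dur = dur, regs = list(
        regimen("pemetrexed", 500, "per_bsa", 21, doses_per_month = q3w),
        regimen("cisplatin", 75, "per_bsa", 21, doses_per_month = q3w))),
      list(w = mix$p_carbo, dur = dur, regs = list(
        regimen("pemetrexed", 500, "per_bsa", 21, doses_per_month = q3w),
        regimen("carboplatin", 5, "auc_calvert", 21, doses_per_month = q3w))))
  } else {
    di <- mix$durations[["c_immuno"]]; dc <- mix$durations[["c_chemo"]]
    list(
      list(w = mix$p_immuno * mix$p_nivo_mono, dur = di, regs = list(
        regimen("nivolumab", 3, "per_kg", 14, doses_per_month = q2w))),
      list(w = mix$p_immuno * (1 - mix$p_nivo_mono), dur = di, regs = list(
        regimen("nivolumab", 3, "per_kg", 14, doses_per_month = q2w),
        regimen("ipilimumab", 1, "per_kg", 42, doses_per_month = q6w))),
      list(w = (1 - mix$p_immuno) * mix$p_vinorelbine, dur = dc, regs = list(
        regimen("vinorelbine", 25, "per_bsa", 21, days_dosed = 2,
                doses_per_month = d1d8))),
      list(w = (1 - mix$p_immuno) * (1 - mix$p_vinorelbine), dur = dc, regs = list(
        regimen("gemcitabine", 1000, "per_bsa", 21, days_dosed = 2,
                doses_per_month = d1d8))))
  }
}

first_line_monthly_cost <- function(arm, mix, pt, prices, dosing = NULL) {
  comps <- first_line_components(arm, mix, dosing)
  sum(vapply(comps, function(cm) cm$w * combo_monthly_cost(cm$regs, pt, prices),
             numeric(1)))
}

second_line_monthly_cost <- function(arm, mix, pt, prices, dosing = NULL) {
  comps <- second_line_components(arm, mix, dosing)
  sum(vapply(comps, function(cm) cm$w * combo_monthly_cost(cm$regs, pt, prices),
             numeric(1)))
}

#' Expected full-course cost of second-line therapy
#'
#' Mixture-weighted expected drug plus administration cost of the arm's
#' second-line strategy over its full stated duration (NI arm:
#' pemetrexed-platinum for 5 months; C arm: immunotherapy for 3 months or
#' mono-chemotherapy for 16 months).
#'
#' @param arm `"NI"` or `"C"`.
#' @param mix A [second_line_mix()].
#' @param pt A [patient()].
#' @param prices A [price_list()].
#' @param dosing Optional per-schedule doses-per-month overrides.
#' @return Expected USD per progressing patient.
#' @export
second_line_course_cost <- function(arm, mix, pt, prices, dosing = NULL) {
  comps <- second_line_components(arm, mix, dosing)
  sum(vapply(comps, function(cm)
    cm$w * cm$dur * combo_monthly_cost(cm$regs, pt, prices), numeric(1)))
}

#' Economic parameter bundle
#'
#' @param pt A [patient()].
#' @param prices A [price_list()].
#' @param mix A [second_line_mix()].
#' @param first_line_duration Months of first-line treatment per arm
#'   (trial medians rounded to whole months).
#' @param dosing Named list of doses-per-month overrides by schedule
#'   (`q2w`, `q3w`, `q6w`, `d1d8`); `NULL` entries fall back to continuous
#'   calendar-month accrual.
#' @param second_line_method `"transition"` charges one cycle of second-line
#'   therapy at progression (a transition cost); `"course"` charges the
#'   expected full-course cost as a lump sum at progression.
#' @param followup_in_pd Charge the follow-up visit fee during the progressed
#'   state as well as the progression-free state.
#' @export
econ_params <- function(pt = patient(), prices = price_list(),
                        mix = second_line_mix(),
                        first_line_duration = c(NI = 6, C = 4),
                        dosing = NULL,
                        second_line_method = c("transition", "course"),
                        followup_in_pd = TRUE) {
  structure(list(pt = pt, prices = prices, mix = mix,
                 first_line_duration = first_line_duration, dosing = dosing,
                 second_line_method = match.arg(second_line_method),
                 followup_in_pd = isTRUE(followup_in_pd)),
            class = "econ_params")
}

#' Accrue discounted direct medical costs along a cohort trace
#'
#' Per cycle: first-line drug plus administration cost against
#' progression-free occupancy while within the arm's first-line duration;
#' follow-up fee against alive occupancy; second-line cost against the newly
#' progressing fraction (one cycle of therapy, or the expected full course,
#' by `second_line_method`); the expected AE management cost once in cycle 1,
#' undiscounted. All other components are discounted with the trace's
#' discount factors.
#'
#' @param arm An [arm_model()].
#' @param trace A [run_trace()] result for the same arm and configuration.
#' @param econ An [econ_params()].
#' @param util A [health_utilities()] (for the AE incidences).
#' @return Object of class `cost_trace`: per-cycle breakdown
#'   (`first_line`, `followup`, `second_line`, `ae`, `total`) with attribute
#'   `total` (discounted USD).
#' @export
total_cost_trace <- function(arm, trace, econ = econ_params(),
                             util = health_utilities()) {
  stopifnot(inherits(trace, "state_trace"))
  cfg <- attr(trace, "cfg")
  if (nrow(trace) != cfg$horizon)
    stop("trace and engine configuration horizons disagree", call. = FALSE)
  flc <- first_line_monthly_cost(arm$name, econ$mix, econ$pt, econ$prices, econ$dosing)
  fl_dur <- econ$first_line_duration[[arm$name]]
  fl <- ifelse(trace$time < fl_dur, flc * trace$occ_pfs * trace$df, 0)
  alive <- trace$occ_pfs + if (econ$followup_in_pd) trace$occ_pd else 0
  fu <- econ$prices$followup * alive * trace$df
  sl_unit <- switch(econ$second_line_method,
    transition = second_line_monthly_cost(arm$name, econ$mix, econ$pt,
                                          econ$prices, econ$dosing),
    course = second_line_course_cost(arm$name, econ$mix, econ$pt,
                                     econ$prices, econ$dosing))
  sl <- sl_unit * trace$new_prog * trace$df
  ae <- c(ae_first_cycle_cost(arm$name, econ$prices, util),
          numeric(nrow(trace) - 1L))
  out <- data.frame(cycle = trace$cycle, first_line = fl, followup = fu,
                    second_line = sl, ae = ae, total = fl + fu + sl + ae)
  structure(out, total = sum(out$total), class = c("cost_trace", "data.frame"))
}

#' @export
print.cost_trace <- function(x, ...) {
  cat(sprintf("<cost_trace> %d cycles, total discounted cost %.2f USD\n",
              nrow(x), attr(x, "total")))
  comp <- colSums(x[, c("first_line", "followup", "second_line", "ae")])
  cat(sprintf("  first-line %.0f | follow-up %.0f | second-line %.0f | AE %.0f\n",
              comp[1], comp[2], comp[3], comp[4]))
  invisible(x)
}
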