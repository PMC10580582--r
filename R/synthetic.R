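#' Specification of a synthetic two-arm trial
#'
#' Arm sizes follow the source trial: 303/302 (all randomized), 229/226
#' (epithelioid), 74/76 (non-epithelioid). Patients accrue uniformly over the
#' accrual window and are administratively censored at the maximum follow-up
#' time measured from study start; the 18/36-month defaults echo a trial
#' followed for at least three years.
#'
#' @param arm_sizes Named list of `c(NI =, C =)` sizes per population.
#' @param accrual Accrual window, months.
#' @param max_followup Maximum follow-up from study start, months.
#' @param seed Base RNG seed.
#' @export
trial_spec <- function(arm_sizes = list(A = c(NI = 303, C = 302),
                                        E = c(NI = 229, C = 226),
                                        N = c(NI = 74, C = 76)),
                       accrual = 18, max_followup = 36, seed = 743L) {
  stopifnot(all(unlist(arm_sizes) > 0), max_followup > 0, accrual >= 0)
  structure(list(arm_sizes = arm_sizes, accrual = accrual,
                 max_followup = max_followup, seed = as.integer(seed)),
            class = "trial_spec")
}

#' Simulate one trial arm as pseudo-IPD
#'
#' Event times are drawn from the given survival distribution by inverse
#' transform; entry times are uniform over the accrual window; follow-up is
#' administratively censored at `max_followup` minus the entry time.
#'
#' @param dist A [parametric_survival()].
#' @param n Arm size.
#' @param accrual Accrual window, months (0 = simultaneous entry).
#' @param max_followup Maximum follow-up from study start, months (may be
#'   `Inf`).
#' @param seed Optional seed; the same spec and seed reproduce the same arm.
#' @return Data frame `time`, `event`.
#' @export
simulate_arm_ipd <- function(dist, n, accrual = 18, max_followup = 36,
                             seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  t_event <- qsurv(dist, stats::runif(n))
  entry <- if (accrual > 0) stats::runif(n, 0, accrual) else numeric(n)
  t_cens <- max_followup - entry
  if (any(t_cens <= 0))
    stop("'max_followup' must exceed every entry time", call. = FALSE)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Build the synthetic end-to-end fixture
#'
#' Simulates all six arm/population combinations from the configured
#' overall-survival distributions, digitises each Kaplan-Meier curve at
#' monthly resolution and emits quarterly number-at-risk tables — the input
#' set on which curve reconstruction, fitting and selection are exercised
#' without any external data.
#'
#' @param spec A [trial_spec()].
#' @param config A `cea_config` supplying the true distributions.
#' @return Nested list `fixture[[population]][[arm]]` with elements `ipd`,
#'   `curve`, `risk`, `truth`.
#' @export
make_checkmate_fixture <- function(spec = trial_spec(),
                                   config = default_config()) {
  out <- list()
  seed_off <- 0L
  for (pop in names(spec$arm_sizes)) {
    out[[pop]] <- list()
    for (arm in c("NI", "C")) {
      seed_off <- seed_off + 1L
      truth <- as_parametric_survival(config$survival$os[[pop]][[arm]])
      ipd <- simulate_arm_ipd(truth, spec$arm_sizes[[pop]][[arm]],
                              spec$accrual, spec$max_followup,
                              seed = spec$seed + seed_off)
      km <- km_estimate(ipd)
      out[[pop]][[arm]] <- list(
        ipd = ipd,
        curve = digitize_km(km, by = 1),
        risk = risk_table_from_ipd(ipd, seq(0, spec$max_followup, by = 3)),
        truth = truth)
    }
  }
  structure(out, spec = spec, class = "checkmate_fixture")
}

#' @export
print.checkmate_fixture <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("<checkmate_fixture> %d populations x 2 arms; accrual %g mo, max follow-up %g mo, seed %d\n",
              length(x), spec$accrual, spec$max_followup, spec$seed))
  for (pop in names(x))
    cat(sprintf("  %s: NI n = %d, C n = %d\n", pop,
                nrow(x[[pop]]$NI$ipd), nrow(x[[pop]]$C$ipd)))
  invisible(x)
}

#' Write a fixture to the delimited interchange formats
#'
#' @param fixture A [make_checkmate_fixture()] result.
#' @param dir Output directory; files are named
#'   `<population>_<arm>_{ipd,curve,risk}.tsv`.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pop in names(fixture)) for (arm in names(fixture[[pop]])) {
    el <- fixture[[pop]][[arm]]
    stem <- file.path(dir, paste0(pop, "_", arm, "_"))
    write_psm_table(el$ipd, paste0(stem, "ipd.tsv"))
    write_psm_table(el$curve, paste0(stem, "curve.tsv"))
    write_psm_table(el$risk, paste0(stem, "risk.tsv"))
  }
  invisible(dir)
}

#' Reconstruction-and-selection pipeline on digitised inputs
#'
#' Reads a digitised curve and (optionally) a number-at-risk table, rebuilds
#' pseudo-IPD with the Guyot algorithm, computes the product-limit estimate
#' and runs six-family selection. When `out_dir` is given, the pseudo-IPD and
#' the ranking table are written as tab-separated text.
#'
#' @param curve_file Path to a `time`/`survival` table.
#' @param risk_file Optional path to a `time`/`n_risk` table.
#' @param n0 Initial arm size (needed when `risk_file` is absent).
#' @param out_dir Optional output directory.
#' @return List with `ipd`, `km`, `selection`.
#' @export
run_reconstruction <- function(curve_file, risk_file = NULL, n0 = NULL,
                               out_dir = NULL) {
  curve <- read_digitized_curve(curve_file)
  risk <- if (!is.null(risk_file)) read_risk_table(risk_file)
  ipd <- reconstruct_ipd(curve, risk, n0 = n0)
  km <- km_estimate(ipd)
  sel <- select_distribution(ipd$time, ipd$event)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_psm_table(ipd, file.path(out_dir, "reconstructed_ipd.tsv"))
    write_psm_table(sel$table, file.path(out_dir, "distribution_ranking.tsv"))
  }
  list(ipd = ipd, km = km, selection = sel)
}
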