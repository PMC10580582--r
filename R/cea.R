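#' Run the cost-effectiveness analysis for one population
#'
#' Builds both treatment arms for the requested histology population from a
#' run configuration, runs the partitioned survival trace and the cost
#' accrual, and returns per-arm discounted life years, QALYs and costs with
#' the incremental comparison (NI vs C) and its ICER.
#'
#' @param config A [default_config()]-style `cea_config`.
#' @param population `"A"` (all randomized), `"E"` (epithelioid) or `"N"`
#'   (non-epithelioid).
#' @return Object of class `cea`.
#' @examples
#' res <- run_cea(default_config(), "A")
#' print(res)
#' @export
run_cea <- function(config = default_config(), population = c("A", "E", "N")) {
  population <- match.arg(population)
  en <- config$engine
  cfg <- engine_config(en$cycle_length, en$horizon, en$discount_rate, en$wtp,
                       en$midpoint, en$background_mortality)
  util <- config_utilities(config)
  econ <- config_econ(config)
  arms <- lapply(c(NI = "NI", C = "C"), function(a) {
    arm <- arm_model(a, config$survival$pfs[[a]],
                     config$survival$os[[population]][[a]], population)
    trace <- run_trace(arm, cfg, util)
    cost <- total_cost_trace(arm, trace, econ, util)
    list(arm = arm, trace = trace, cost = cost,
         ly = attr(trace, "ly"), qaly = attr(trace, "qaly"),
         total_cost = attr(cost, "total"))
  })
  dc <- arms$NI$total_cost - arms$C$total_cost
  dq <- arms$NI$qaly - arms$C$qaly
  ic <- icer(dc, dq)
  structure(list(population = population, wtp = en$wtp, arms = arms,
                 delta_ly = arms$NI$ly - arms$C$ly,
                 delta_cost = dc, delta_qaly = dq,
                 icer = ic$icer, status = ic$status),
            class = "cea")
}

config_utilities <- function(config) {
  ut <- config$utilities
  health_utilities(ut$u_pfs, ut$u_pd, ut$u_death,
                   unlist(ut$disutility),
                   lapply(ut$incidence, unlist))
}

config_econ <- function(config) {
  tr <- config$treatment
  econ_params(
    pt = patient(config$patient$weight, config$patient$bsa,
                 config$patient$crcl, config$patient$age),
    prices = price_list(unlist(config$prices$drugs), config$prices$admin_iv,
                        config$prices$followup, unlist(config$prices$ae_cost)),
    mix = second_line_mix(tr$mix$p_carbo, tr$mix$p_immuno, tr$mix$p_nivo_mono,
                          tr$mix$p_vinorelbine,
                          unlist(tr$second_line_duration)),
    first_line_duration = unlist(tr$first_line_duration),
    dosing = tr$dosing,
    second_line_method = tr$second_line_method,
    followup_in_pd = tr$followup_in_pd)
}

#' @export
print.cea <- function(x, ...) {
  cat(sprintf("Cost-effectiveness analysis, population %s (NI vs C)\n", x$population))
  tab <- summary(x)
  print(format(tab, big.mark = ",", digits = 4), row.names = FALSE)
  lab <- switch(x$status,
    icer = sprintf("ICER %s USD/QALY vs WTP %s USD/QALY",
                   format(round(x$icer), big.mark = ","),
                   format(x$wtp, big.mark = ",")),
    dominant = "NI dominates C (cheaper, more effective)",
    dominated = "NI is dominated by C (costlier, less effective)",
    undefined = "equal QALYs: ICER undefined")
  cat(lab, "\n")
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  a <- object$arms
  data.frame(
    strategy = c("NI", "C", "Incremental (NI vs C)"),
    life_years = c(a$NI$ly, a$C$ly, object$delta_ly),
    cost = c(a$NI$total_cost, a$C$total_cost, object$delta_cost),
    qalys = c(a$NI$qaly, a$C$qaly, object$delta_qaly),
    icer = c(NA, NA, object$icer))
}

#' Base-case summary across populations
#'
#' Runs [run_cea()] for each requested population and stacks the per-arm and
#' incremental rows into one summary table. When `out_dir` is given the table
#' is written as tab-separated text and the run is logged (seed-free
#' deterministic run: configuration hash and package version).
#'
#' @param config A `cea_config`.
#' @param populations Subset of `c("A", "E", "N")`.
#' @param out_dir Optional output directory.
#' @return Object of class `cea_summary` (a data frame); the individual `cea`
#'   objects are attached as attribute `results`.
#' @export
run_base_case <- function(config = default_config(),
                          populations = c("A", "E", "N"), out_dir = NULL) {
  populations <- match.arg(populations, several.ok = TRUE)
  if ("N" %in% populations && !is.null(config$notes$cn_os_gamma))
    message("note: ", config$notes$cn_os_gamma)
  res <- lapply(populations, function(p) run_cea(config, p))
  names(res) <- populations
  tab <- do.call(rbind, lapply(populations, function(p) {
    s <- summary(res[[p]]); s$population <- p
    s[, c("population", setdiff(names(s), "population"))]
  }))
  rownames(tab) <- NULL
  out <- structure(tab, results = res, class = c("cea_summary", "data.frame"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_psm_table(round_presentation(tab), file.path(out_dir, "base_case.tsv"))
    log_run("base-case", config)
  }
  out
}

# presentation rounding: whole USD, 2-dp QALYs/LYs, whole USD/QALY
round_presentation <- function(tab) {
  tab$cost <- round(tab$cost)
  tab$life_years <- round(tab$life_years, 2)
  tab$qalys <- round(tab$qalys, 2)
  tab$icer <- round(tab$icer)
  tab
}

#' @export
print.cea_summary <- function(x, ...) {
  cat("Base-case cost-effectiveness summary (discounted)\n")
  print(format(round_presentation(as.data.frame(x)), big.mark = ","),
        row.names = FALSE)
  invisible(x)
}

# FNV-1a hash of the canonical YAML form, for run logs; the xor only touches
# the low byte, keeping the accumulator a double below 2^32
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(config)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- ((h - low + bitwXor(as.integer(low), as.integer(b))) * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

log_run <- function(what, config, seed = NULL) {
  message(sprintf("psmcea %s run | config %s%s | psmcea %s",
                  what, config_hash(config),
                  if (is.null(seed)) "" else sprintf(" | seed %d", seed),
                  as.character(utils::packageVersion("psmcea"))))
}
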