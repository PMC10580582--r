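#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the deterministic model for each parameter at its low and at its
#' high value, all other parameters held at base, and records the resulting
#' ICERs. Rows are sorted by descending spread `|ICER(high) - ICER(low)|`,
#' the tornado-diagram ordering.
#'
#' @param config A `cea_config`.
#' @param population `"A"`, `"E"` or `"N"`.
#' @param ranges Parameter table from [param_ranges()] (or a subset of it).
#' @return Object of class `owsa_result`: data frame `id`, `low`, `high`,
#'   `icer_low`, `icer_high`, `spread`, with the base ICER as attribute
#'   `base_icer`.
#' @export
owsa <- function(config = default_config(), population = "A",
                 ranges = param_ranges(config)) {
  if (any(ranges$low > ranges$base | ranges$base > ranges$high))
    stop("invalid range: 'low <= base <= high' violated", call. = FALSE)
  base <- run_cea(config, population)
  one <- function(id, value) {
    run_cea(set_param(config, id, value), population)$icer
  }
  icer_low <- mapply(one, ranges$id, ranges$low)
  icer_high <- mapply(one, ranges$id, ranges$high)
  out <- data.frame(id = ranges$id, low = ranges$low, high = ranges$high,
                    icer_low = icer_low, icer_high = icer_high,
                    spread = abs(icer_high - icer_low))
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, base_icer = base$icer, population = population,
            wtp = base$wtp, class = c("owsa_result", "data.frame"))
}

#' @export
print.owsa_result <- function(x, n = 10, ...) {
  cat(sprintf("One-way sensitivity analysis, population %s (base ICER %s USD/QALY)\n",
              attr(x, "population"),
              format(round(attr(x, "base_icer")), big.mark = ",")))
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("... and %d more parameters\n", nrow(x) - n))
  invisible(x)
}

#' @export
plot.owsa_result <- function(x, n = 12, main = NULL, ...) {
  d <- utils::head(as.data.frame(x), n)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_icer")
  op <- graphics::par(mar = c(4.5, 12, 3, 1)); on.exit(graphics::par(op))
  lo <- pmin(d$icer_low, d$icer_high); hi <- pmax(d$icer_low, d$icer_high)
  graphics::plot(NA, xlim = range(c(lo, hi, base)), ylim = c(0.5, nrow(d) + 0.5),
                 yaxt = "n", xlab = "ICER (USD/QALY)", ylab = "",
                 main = main %||% sprintf("Tornado diagram, population %s",
                                          attr(x, "population")), ...)
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi, seq_len(nrow(d)) + 0.35,
                 col = "steelblue", border = "grey30")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$id, las = 1, cex.axis = 0.7)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold (break-even) price search by bisection
#'
#' Finds the value of a price parameter at which the ICER equals a target
#' (typically the willingness-to-pay threshold), assuming the ICER is
#' monotone in the parameter over the bracket. The initial bracket is
#' `[0, 4 x base]`, doubled up to `64 x base` while no sign change is found;
#' bisection stops when `|ICER - target| < tol`.
#'
#' @param config A `cea_config`.
#' @param population Population selector.
#' @param param Parameter id, e.g. `"prices.drugs.pemetrexed"`.
#' @param target Target ICER, USD/QALY; defaults to the configured WTP.
#' @param tol Convergence tolerance on the ICER, USD/QALY.
#' @return The crossing price (with attribute `icer`).
#' @export
threshold_price <- function(config = default_config(), population = "N",
                            param = "prices.drugs.pemetrexed",
                            target = NULL, tol = 1) {
  target <- target %||% config$engine$wtp
  f <- function(p) run_cea(set_param(config, param, p), population)$icer - target
  base <- get_param(config, param)
  lo <- 0; hi <- max(4 * base, 1e-6)
  flo <- f(lo); fhi <- f(hi)
  while (sign(flo) == sign(fhi) && hi < 64 * base) {
    hi <- 2 * hi; fhi <- f(hi)
  }
  if (sign(flo) == sign(fhi))
    stop(sprintf("no ICER = %s crossing for '%s' in [0, %g]",
                 format(target, big.mark = ","), param, hi), call. = FALSE)
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2; fmid <- f(mid)
    if (abs(fmid) < tol) break
    if (sign(fmid) == sign(flo)) { lo <- mid; flo <- fmid } else { hi <- mid; fhi <- fmid }
  }
  structure(mid, icer = fmid + target)
}

# -- probabilistic sensitivity analysis -------------------------------------

# method-of-moments samplers; sd = (high - low) / 3.92 treats the printed
# range as a 95% interval
psa_sampler <- function(family, base, low, high) {
  sdv <- (high - low) / 3.92
  switch(family,
    fixed = function(n) rep.int(base, n),
    uniform = function(n) stats::runif(n, low, high),
    beta = {
      if (base <= 0 || base >= 1 || sdv^2 >= base * (1 - base))
        function(n) stats::runif(n, low, high)   # degenerate moments
      else {
        nu <- base * (1 - base) / sdv^2 - 1
        a <- base * nu; b <- (1 - base) * nu
        function(n) stats::rbeta(n, a, b)
      }
    },
    gamma = {
      if (base <= 0 || sdv <= 0) function(n) rep.int(base, n)
      else {
        shape <- base^2 / sdv^2; rate <- base / sdv^2
        function(n) stats::rgamma(n, shape, rate)
      }
    },
    stop("unknown PSA family: ", family, call. = FALSE))
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Draws every parameter from its PSA distribution (survival parameters are
#' held fixed; their ranges are not reported in the source table), re-runs
#' both arms per iteration and records the incremental cost and QALYs.
#' Fully reproducible from the seed: parameter vectors are drawn up front in
#' the fixed row order of `ranges` from a single RNG stream.
#'
#' @param config A `cea_config`.
#' @param population Population selector.
#' @param n_iter Iterations (1000 in the base case).
#' @param seed RNG seed; defaults to the configured `psa$seed`.
#' @param ranges Parameter table from [param_ranges()].
#' @return Object of class `psa_result`: data frame `iteration`,
#'   `delta_cost`, `delta_qaly`, with the draw matrix, population, WTP and
#'   seed as attributes.
#' @export
psa_run <- function(config = default_config(), population = "A",
                    n_iter = NULL, seed = NULL, ranges = param_ranges(config)) {
  n_iter <- as.integer(n_iter %||% config$psa$n_iter)
  seed <- as.integer(seed %||% config$psa$seed)
  if (n_iter < 1L) stop("'n_iter' must be at least 1", call. = FALSE)
  set.seed(seed)
  draws <- vapply(seq_len(nrow(ranges)), function(i) {
    s <- psa_sampler(ranges$psa_family[i], ranges$base[i], ranges$low[i],
                     ranges$high[i])
    s(n_iter)
  }, numeric(n_iter))
  draws <- matrix(draws, nrow = n_iter,
                  dimnames = list(NULL, ranges$id))
  res <- vapply(seq_len(n_iter), function(it) {
    cfg_i <- config
    for (j in seq_len(ncol(draws)))
      cfg_i <- set_param(cfg_i, colnames(draws)[j], unname(draws[it, j]))
    r <- run_cea(cfg_i, population)
    c(r$delta_cost, r$delta_qaly)
  }, numeric(2))
  out <- data.frame(iteration = seq_len(n_iter), delta_cost = res[1L, ],
                    delta_qaly = res[2L, ])
  structure(out, draws = draws, population = population,
            wtp = config$engine$wtp, seed = seed,
            class = c("psa_result", "data.frame"))
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(paste0("<psa_result> population %s: %d iterations (seed %d)\n",
                     "  mean dCost %.0f USD, mean dQALY %.4f, ",
                     "P(cost-effective at WTP %s) = %.3f\n"),
              attr(x, "population"), nrow(x), attr(x, "seed"),
              mean(x$delta_cost), mean(x$delta_qaly),
              format(attr(x, "wtp"), big.mark = ","),
              mean(attr(x, "wtp") * x$delta_qaly - x$delta_cost > 0)))
  invisible(x)
}

#' @export
plot.psa_result <- function(x, wtp = attr(x, "wtp"), main = NULL, ...) {
  graphics::plot(x$delta_qaly, x$delta_cost,
                 xlab = "Incremental QALYs", ylab = "Incremental cost (USD)",
                 main = main %||% sprintf("CE plane, population %s",
                                          attr(x, "population")),
                 pch = 16, cex = 0.5, col = "#00000080", ...)
  graphics::abline(a = 0, b = wtp, col = "firebrick", lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey60")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that NI is
#' cost-effective is the fraction of PSA iterations with positive incremental
#' net monetary benefit, `wtp x dQALY - dCost > 0`.
#'
#' @param samples A [psa_run()] result (any data frame with `delta_cost` and
#'   `delta_qaly`).
#' @param wtp Willingness-to-pay grid, USD/QALY.
#' @return Object of class `ceac`: data frame `wtp`, `probability`.
#' @export
ceac <- function(samples, wtp = seq(0, 400000, by = 1000)) {
  if (!is.data.frame(samples) || nrow(samples) < 1L)
    stop("'samples' must contain at least one PSA iteration", call. = FALSE)
  prob <- vapply(wtp, function(l)
    mean(l * samples$delta_qaly - samples$delta_cost > 0), numeric(1))
  structure(data.frame(wtp = wtp, probability = prob),
            population = attr(samples, "population"),
            class = c("ceac", "data.frame"))
}

#' @export
plot.ceac <- function(x, main = NULL, ...) {
  graphics::plot(x$wtp, x$probability, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "Willingness to pay (USD/QALY)",
                 ylab = "P(NI cost-effective)",
                 main = main %||% sprintf("Acceptability curve, population %s",
                                          attr(x, "population") %||% ""), ...)
  invisible(x)
}

#' Orchestrated one-way sensitivity run
#'
#' @param config A `cea_config`.
#' @param population Population selector.
#' @param out_dir Optional directory for `tornado.tsv` and `tornado.png`.
#' @return The [owsa()] result.
#' @export
run_owsa <- function(config = default_config(), population = "A",
                     out_dir = NULL) {
  res <- owsa(config, population)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_psm_table(res, file.path(out_dir, sprintf("tornado_%s.tsv", population)))
    grDevices::png(file.path(out_dir, sprintf("tornado_%s.png", population)),
                   width = 900, height = 700)
    plot(res); grDevices::dev.off()
    log_run("owsa", config)
  }
  res
}

#' Orchestrated probabilistic sensitivity run
#'
#' Runs the PSA, derives the acceptability curve, and (optionally) writes the
#' sample table, CEAC table, scatter and CEAC plots.
#'
#' @inheritParams psa_run
#' @param out_dir Optional output directory.
#' @return List with `psa` and `ceac`.
#' @export
run_psa <- function(config = default_config(), population = "A",
                    n_iter = NULL, seed = NULL, out_dir = NULL) {
  res <- psa_run(config, population, n_iter, seed)
  cc <- ceac(res)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_psm_table(res, file.path(out_dir, sprintf("psa_samples_%s.tsv", population)))
    write_psm_table(cc, file.path(out_dir, sprintf("ceac_%s.tsv", population)))
    grDevices::png(file.path(out_dir, sprintf("ce_plane_%s.png", population)),
                   width = 700, height = 600)
    plot(res); grDevices::dev.off()
    grDevices::png(file.path(out_dir, sprintf("ceac_%s.png", population)),
                   width = 700, height = 500)
    plot(cc); grDevices::dev.off()
    log_run("psa", config, seed = attr(res, "seed"))
  }
  list(psa = res, ceac = cc)
}
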