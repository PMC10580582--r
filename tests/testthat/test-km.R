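test_that("product-limit estimator matches hand computation", {
  ipd <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0))
  km <- km_estimate(ipd)
  expect_equal(km_surv_at(km, 1), 2 / 3)
  expect_equal(km_surv_at(km, 2), 1 / 3)
  expect_equal(km_surv_at(km, 3), 1 / 3)      # censoring does not drop the curve
  expect_equal(km_surv_at(km, 0.5), 1)

  all_cens <- km_estimate(data.frame(time = c(2, 5, 9), event = c(0, 0, 0)))
  expect_true(all(all_cens$survival == 1))

  one <- km_estimate(data.frame(time = 5, event = 1))
  expect_equal(km_surv_at(one, c(4.999, 5)), c(1, 0))

  expect_error(km_estimate(data.frame(time = numeric(0), event = integer(0))),
               "at least one")
})

test_that("digitisation and risk tables describe the step function faithfully", {
  ipd <- data.frame(time = c(2, 4, 4, 7, 12), event = c(1, 1, 0, 1, 0))
  km <- km_estimate(ipd)
  curve <- digitize_km(km, by = 1)
  expect_equal(curve$time[1], 0)
  expect_equal(curve$survival[1], 1)
  expect_true(all(diff(curve$survival) <= 0))
  expect_equal(curve$survival[curve$time == 3], km_surv_at(km, 3))
  # number at risk at s counts everyone still under observation (time >= s)
  risk <- risk_table_from_ipd(ipd, c(0, 3, 6, 9, 12))
  expect_equal(risk$n_risk, c(5, 4, 2, 1, 1))
})

test_that("reconstruction is exact when there is no censoring", {
  set.seed(9)
  ev <- sort(round(rexp(20, 0.08), 2))
  km <- km_estimate(data.frame(time = ev, event = 1))
  curve <- rbind(data.frame(time = 0, survival = 1),
                 data.frame(time = km$time, survival = km$survival))
  # at-risk counts reported just before each event time
  risk <- risk_table_from_ipd(data.frame(time = ev, event = 1), c(0, ev))
  # clicks sit at the true event times, so events belong at the clicks
  ipd <- reconstruct_ipd(curve, risk, event_placement = "at_click")
  expect_equal(nrow(ipd), 20L)
  expect_equal(sum(ipd$event), 20L)
  expect_equal(sort(ipd$time[ipd$event == 1]), ev, tolerance = 1e-12)
})

test_that("reconstruction returns one record per initial patient", {
  fix <- make_checkmate_fixture(trial_spec(seed = 201))
  el <- fix$A$NI
  ipd <- reconstruct_ipd(el$curve, el$risk)
  expect_equal(nrow(ipd), 303L)               # NI arm size, all-randomized
  el2 <- fix$A$C
  expect_equal(nrow(reconstruct_ipd(el2$curve, el2$risk)), 302L)
})

test_that("reconstructed event/censor splits reproduce the risk table where converged", {
  fix <- make_checkmate_fixture(trial_spec(seed = 202))
  el <- fix$E$C
  ipd <- reconstruct_ipd(el$curve, el$risk)
  di <- attr(ipd, "intervals")
  conv <- di[!is.na(di$n_risk_target), ]
  # converged intervals reproduce the table exactly; most intervals converge
  expect_equal(conv$n_risk_achieved[conv$converged],
               conv$n_risk_target[conv$converged])
  expect_gte(mean(conv$converged), 0.7)
})

test_that("simulate -> digitise -> reconstruct -> fit recovers the truth", {
  true <- parametric_survival("weibull_ph", 0.0242, 1.128)
  ipd0 <- simulate_arm_ipd(true, 300, accrual = 18, max_followup = 36, seed = 99)
  km0 <- km_estimate(ipd0)
  curve <- digitize_km(km0, by = 1)
  risk <- risk_table_from_ipd(ipd0, seq(0, 36, by = 3))
  ipd1 <- reconstruct_ipd(curve, risk)
  expect_equal(nrow(ipd1), 300L)

  # round-trip fidelity of the survival curve at the digitisation resolution
  km1 <- km_estimate(ipd1)
  grid <- seq(0, 36, by = 1)
  expect_lt(max(abs(km_surv_at(km0, grid) - km_surv_at(km1, grid))), 0.02)

  # parameter recovery in expectation: a single n = 300 arm carries sampling
  # noise well above 5% on lambda (the direct MLE on the uncensored times
  # shows the same scatter), so unbiasedness is what the pipeline can promise
  est <- vapply(1:10, function(i) {
    ip0 <- simulate_arm_ipd(true, 300, accrual = 18, max_followup = 36,
                            seed = 3000 + i)
    cv <- digitize_km(km_estimate(ip0), by = 1)
    rk <- risk_table_from_ipd(ip0, seq(0, 36, by = 3))
    ip1 <- reconstruct_ipd(cv, rk)
    coef(fit_parametric(ip1$time, ip1$event, "weibull_ph"))
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 0.0242) / 0.0242, 0.05)
  expect_lt(abs(mean(est[2, ]) - 1.128) / 1.128, 0.05)
})

test_that("invalid digitised inputs are rejected with informative errors", {
  good <- data.frame(time = c(0, 1, 2), survival = c(1, 0.8, 0.6))
  risk_up <- data.frame(time = c(0, 1), n_risk = c(10, 12))
  expect_error(reconstruct_ipd(good, risk_up), "increases")
  bad_start <- data.frame(time = c(1, 2), survival = c(1, 0.8))
  expect_error(reconstruct_ipd(bad_start, data.frame(time = 0, n_risk = 5)),
               "start at")
  rising <- data.frame(time = c(0, 1, 2), survival = c(1, 0.7, 0.9))
  expect_error(reconstruct_ipd(rising, data.frame(time = 0, n_risk = 5)),
               "non-increasing")
  expect_warning(reconstruct_ipd(good, risk = NULL, n0 = 10), "no risk table")
})

test_that("interchange files round-trip through the delimited formats", {
  dir <- withr::local_tempdir()
  curve <- data.frame(time = c(0, 1, 2), survival = c(1, 0.9, 0.7))
  risk <- data.frame(time = c(0, 2), n_risk = c(50, 30))
  ipd <- data.frame(time = c(0.5, 1.2), event = c(1L, 0L))
  write_psm_table(curve, file.path(dir, "c.tsv"))
  write_psm_table(risk, file.path(dir, "r.tsv"))
  write_psm_table(ipd, file.path(dir, "i.tsv"))
  expect_equal(read_digitized_curve(file.path(dir, "c.tsv")), curve)
  expect_equal(read_risk_table(file.path(dir, "r.tsv")), risk)
  expect_equal(read_ipd(file.path(dir, "i.tsv")), ipd)
})
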