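test_that("all patients enter progression-free and the clamp rule holds", {
  d <- table1_dists()
  arm <- arm_model("NI", d$ni_pfs, d$ni_os_a, "A")
  expect_equal(unname(occupancy(arm, 0)), matrix(c(1, 0, 0), 1))
  # an arm whose raw PFS exceeds OS: occupancy must clamp PFS to OS
  slow_pfs <- parametric_survival("exponential", 0.01)
  fast_os <- parametric_survival("exponential", 0.1)
  arm2 <- arm_model("NI", slow_pfs, fast_os, "A")
  occ <- occupancy(arm2, c(5, 20, 60))
  expect_equal(occ[, "pfs"], psurv(fast_os, c(5, 20, 60)))
  expect_equal(occ[, "pd"], rep(0, 3))
  expect_equal(occ[, "dead"], 1 - psurv(fast_os, c(5, 20, 60)))
})

test_that("occupancy composes the fitted curves at 12 months", {
  d <- table1_dists()
  arm <- arm_model("NI", d$ni_pfs, d$ni_os_a, "A")
  occ <- occupancy(arm, 12)
  os12 <- 0.671098769812
  expect_equal(unname(occ[, "dead"]), 1 - os12, tolerance = 1e-9)
  expect_equal(unname(occ[, "pfs"]),
               min(psurv(d$ni_pfs, 12), os12), tolerance = 1e-9)
})

test_that("state occupancy conserves mass and death is monotone in every population", {
  cfg <- default_config()
  en <- engine_config()
  for (pop in c("A", "E", "N")) for (a in c("NI", "C")) {
    arm <- arm_model(a, cfg$survival$pfs[[a]], cfg$survival$os[[pop]][[a]], pop)
    tr <- run_trace(arm, en)
    expect_true(all(abs(tr$occ_pfs + tr$occ_pd + tr$occ_dead - 1) <= 1e-12),
                info = paste(pop, a))
    expect_true(all(diff(tr$occ_dead) >= 0), info = paste(pop, a))
    expect_true(all(tr$occ_pd >= 0), info = paste(pop, a))
  }
})

test_that("a fully alive single cycle accrues one undiscounted month", {
  near_one <- parametric_survival("exponential", 1e-12)
  arm <- arm_model("NI", near_one, near_one, "A")
  cfg <- engine_config(horizon = 1, discount_rate = 0)
  util <- health_utilities(u_pfs = 1, u_pd = 1,
    ae_incidence = list(NI = c(asthenia = 0, anemia = 0, neutropenia = 0),
                        C  = c(asthenia = 0, anemia = 0, neutropenia = 0)))
  tr <- run_trace(arm, cfg, util)
  expect_equal(attr(tr, "ly"), 1 / 12, tolerance = 1e-9)
  expect_equal(attr(tr, "qaly"), 1 / 12, tolerance = 1e-9)
})

test_that("cycle-start life years match the geometric closed form", {
  lam <- 0.05; T <- 24
  d <- parametric_survival("exponential", lam)
  arm <- arm_model("C", d, d, "A")
  cfg <- engine_config(horizon = T, discount_rate = 0, midpoint = FALSE)
  tr <- run_trace(arm, cfg)
  expect_equal(attr(tr, "ly"), (1 - exp(-lam * T)) / (12 * (1 - exp(-lam))),
               tolerance = 1e-10)
})

test_that("midpoint life years agree with fine-grid integration of OS", {
  d <- table1_dists()
  for (os in list(d$ni_os_a, d$c_os_a)) {
    arm <- arm_model("NI", d$ni_pfs, os, "A")
    tr <- run_trace(arm, engine_config())
    grid <- seq(0, 120, length.out = 1000)
    s <- psurv(os, grid) * 1.05^(-grid / 12)
    ly_int <- sum((s[-1] + s[-length(s)]) / 2 * diff(grid)) / 12
    expect_lt(abs(attr(tr, "ly") - ly_int) / ly_int, 0.005)
  }
})

test_that("discounting monotonically shrinks outcomes", {
  d <- table1_dists()
  arm <- arm_model("NI", d$ni_pfs, d$ni_os_a, "A")
  res <- sapply(c(0, 0.04, 0.08), function(r) {
    tr <- run_trace(arm, engine_config(discount_rate = r))
    c(attr(tr, "ly"), attr(tr, "qaly"))
  })
  expect_true(all(diff(res[1, ]) < 0))
  expect_true(all(diff(res[2, ]) < 0))
})

test_that("QALYs equal life years under unit utilities and no AEs", {
  d <- table1_dists()
  arm <- arm_model("C", d$c_pfs, d$c_os_a, "A")
  util <- health_utilities(u_pfs = 1, u_pd = 1,
    ae_incidence = list(NI = c(asthenia = 0, anemia = 0, neutropenia = 0),
                        C  = c(asthenia = 0, anemia = 0, neutropenia = 0)))
  tr <- run_trace(arm, engine_config(), util)
  expect_identical(attr(tr, "ly"), attr(tr, "qaly"))
})

test_that("background mortality floors the death hazard", {
  d <- table1_dists()
  arm <- arm_model("NI", d$ni_pfs, d$ni_os_a, "A")
  occ0 <- occupancy(arm, c(12, 60))
  occ1 <- occupancy(arm, c(12, 60), background_mortality = 0.002)
  expect_true(all(occ1[, "dead"] > occ0[, "dead"]))
  tr <- run_trace(arm, engine_config(background_mortality = 0.002))
  expect_true(all(abs(tr$occ_pfs + tr$occ_pd + tr$occ_dead - 1) <= 1e-12))
})

test_that("ICER arithmetic and dominance flags", {
  expect_equal(icer(38023, 0.10)$icer, 380230)
  expect_equal(icer(38023, 0.10)$status, "icer")
  expect_equal(icer(-100, 0.10)$status, "dominant")
  expect_equal(icer(100, -0.05)$status, "dominated")
  expect_equal(icer(100, 0)$status, "undefined")
  expect_true(is.na(icer(100, 0)$icer))
})

test_that("engine configuration enforces its invariants", {
  expect_error(engine_config(discount_rate = 0.09), "0.08")
  expect_error(engine_config(discount_rate = -0.01), "0.08")
  expect_error(engine_config(horizon = 0))
})
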