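test_that("dose rules reproduce the protocol doses for the model patient", {
  pt <- patient()                                      # 65 kg, 1.72 m2, CrCl 60
  expect_equal(dose_mg(regimen("nivolumab", 3, "per_kg", 14), pt), 195)
  expect_equal(dose_mg(regimen("pemetrexed", 500, "per_bsa", 21), pt), 860)
  # Calvert formula: AUC x (CrCl + 25)
  expect_equal(dose_mg(regimen("carboplatin", 5, "auc_calvert", 21), pt), 425)
  expect_equal(dose_mg(regimen("x", 100, "flat", 21), pt), 100)
})

test_that("per-dose and per-month drug costs follow the price schedule", {
  pt <- patient(); pr <- price_list()
  nivo <- regimen("nivolumab", 3, "per_kg", 14)
  # 195 mg x 15.96 USD/mg per dose
  expect_equal(per_cycle_drug_cost(nivo, pt, pr, admin = FALSE) /
                 psmcea:::doses_per_month(nivo), 3112.20)
  ipi <- regimen("ipilimumab", 1, "per_kg", 42)
  expect_equal(per_cycle_drug_cost(ipi, pt, pr, admin = FALSE) /
                 psmcea:::doses_per_month(ipi), 5067.40)
  # continuous calendar-month accrual default: 30.4375/42 doses per month
  expect_equal(psmcea:::doses_per_month(ipi), 30.4375 / 42, tolerance = 1e-12)
  # a free drug costs administration fees only
  pr0 <- price_list(drugs = c(nivolumab = 0))
  expect_equal(per_cycle_drug_cost(nivo, pt, pr0),
               7.83 * psmcea:::doses_per_month(nivo))
  expect_error(per_cycle_drug_cost(regimen("unknown", 1, "flat", 21), pt, pr),
               "unknown")
})

test_that("one administration fee is charged per visit day, not per drug", {
  pt <- patient(); pr <- price_list()
  nivo <- regimen("nivolumab", 3, "per_kg", 14)
  ipi <- regimen("ipilimumab", 1, "per_kg", 42)
  combo <- combo_monthly_cost(list(nivo, ipi), pt, pr)
  singles <- per_cycle_drug_cost(nivo, pt, pr, admin = FALSE) +
             per_cycle_drug_cost(ipi, pt, pr, admin = FALSE)
  expect_equal(combo - singles, 7.83 * psmcea:::doses_per_month(nivo))
})

test_that("first-cycle AE costs are incidence-weighted sums", {
  pr <- price_list(); util <- health_utilities()
  expect_equal(ae_first_cycle_cost("C", pr, util), 126.265904, tolerance = 1e-9)
  expect_equal(ae_first_cycle_cost("NI", pr, util), 4.564193, tolerance = 1e-9)
  u0 <- health_utilities(ae_incidence = list(
    NI = c(asthenia = 0, anemia = 0, neutropenia = 0),
    C = c(asthenia = 0, anemia = 0, neutropenia = 0)))
  expect_equal(ae_first_cycle_cost("C", pr, u0), 0)
})

test_that("second-line course costs follow the mixture arithmetic", {
  pt <- patient(); pr <- price_list()
  # chemotherapy-only C arm, vinorelbine only: 43 mg x 1.52 = 65.36 per dose
  mx <- second_line_mix(p_immuno = 0, p_vinorelbine = 1)
  vin <- regimen("vinorelbine", 25, "per_bsa", 21, days_dosed = 2)
  dpm <- psmcea:::doses_per_month(vin)               # 2 x 30.4375 / 21
  expect_equal(second_line_course_cost("C", mx, pt, pr),
               (65.36 + 7.83) * dpm * 16, tolerance = 1e-9)
  # immunotherapy-only, nivolumab monotherapy for 3 months
  mx2 <- second_line_mix(p_immuno = 1, p_nivo_mono = 1)
  expect_equal(second_line_course_cost("C", mx2, pt, pr),
               (3112.20 + 7.83) * (30.4375 / 14) * 3, tolerance = 1e-9)
  # zero prices leave administration fees only
  pr0 <- price_list(drugs = c(nivolumab = 0, ipilimumab = 0, pemetrexed = 0,
                              cisplatin = 0, carboplatin = 0, vinorelbine = 0,
                              gemcitabine = 0))
  expect_equal(second_line_course_cost("C", mx2, pt, pr0),
               7.83 * (30.4375 / 14) * 3, tolerance = 1e-9)
})

test_that("drug-acquisition costs scale linearly with unit prices", {
  cfg <- default_config()
  arm <- arm_model("NI", cfg$survival$pfs$NI, cfg$survival$os$A$NI, "A")
  tr <- run_trace(arm, engine_config())
  econ1 <- psmcea:::config_econ(cfg)
  cfg2 <- cfg
  cfg2$prices$drugs <- lapply(cfg$prices$drugs, function(p) 2 * p)
  econ2 <- psmcea:::config_econ(cfg2)
  c1 <- total_cost_trace(arm, tr, econ1)
  c2 <- total_cost_trace(arm, tr, econ2)
  # doubling every unit price doubles the drug component of each cost stream
  admin1 <- 7.83 * 2 * tr$occ_pfs * tr$df * (tr$time < 6)      # q2w visits
  drug1_fl <- colSums(c1)["first_line"] - sum(admin1)
  drug2_fl <- colSums(c2)["first_line"] - sum(admin1)
  expect_equal(unname(drug2_fl), unname(2 * drug1_fl), tolerance = 1e-9)
  expect_equal(colSums(c2)["followup"], colSums(c1)["followup"])
  expect_equal(colSums(c2)["ae"], colSums(c1)["ae"])
})

test_that("total cost is monotone in unit prices and first-line duration", {
  cfg <- default_config()
  total_for <- function(cfg) run_cea(cfg, "A")$arms$NI$total_cost
  base <- total_for(cfg)
  for (id in c("prices.drugs.nivolumab", "prices.drugs.ipilimumab",
               "prices.admin_iv", "prices.followup")) {
    up <- total_for(set_param(cfg, id, get_param(cfg, id) * 1.5))
    expect_gt(up, base)
  }
  longer <- cfg; longer$treatment$first_line_duration$NI <- 8
  expect_gt(total_for(longer), base)
})

test_that("identical arms produce identical outcomes", {
  cfg <- default_config()
  arm <- arm_model("C", cfg$survival$pfs$C, cfg$survival$os$A$C, "A")
  tr1 <- run_trace(arm, engine_config())
  tr2 <- run_trace(arm, engine_config())
  expect_identical(attr(tr1, "qaly"), attr(tr2, "qaly"))
  c1 <- total_cost_trace(arm, tr1); c2 <- total_cost_trace(arm, tr2)
  expect_identical(attr(c1, "total"), attr(c2, "total"))
  # equal survival in both arms: the QALY difference vanishes exactly
  cfg$survival$pfs$C <- cfg$survival$pfs$NI
  cfg$survival$os$A$C <- cfg$survival$os$A$NI
  res <- run_cea(cfg, "A")
  # AE profiles still differ between arms; survival-driven QALYs cancel
  ae_gap <- sum(unlist(cfg$utilities$incidence$C) * unlist(cfg$utilities$disutility)) / 12 -
            sum(unlist(cfg$utilities$incidence$NI) * unlist(cfg$utilities$disutility)) / 12
  expect_equal(res$delta_qaly, ae_gap, tolerance = 1e-12)
  expect_equal(res$delta_ly, 0, tolerance = 1e-12)
})

test_that("cost trace validates its inputs", {
  cfg <- default_config()
  arm <- arm_model("NI", cfg$survival$pfs$NI, cfg$survival$os$A$NI, "A")
  tr <- run_trace(arm, engine_config(horizon = 60))
  attr(tr, "cfg") <- engine_config(horizon = 120)
  expect_error(total_cost_trace(arm, tr), "horizon")
  expect_error(price_list(drugs = c(nivolumab = -1)), "non-negative")
  expect_error(second_line_mix(p_immuno = 1.2), "\\[0, 1\\]")
})
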