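test_that("diagnostic work-up costs sum their printed components", {
  p <- bc_primary()
  expect_equal(test_cost(p, "standard"), 55 + 69 + 50)
  expect_equal(test_cost(p, "mri_clp") - test_cost(p, "mri"), 250)
  expect_equal(test_cost(p, "mri") - test_cost(p, "standard"),
               param_get(p, "costs.mri_exam"))
  z <- p
  for (pth in c("costs.specialist_consult_diag", "costs.mmse", "costs.labs",
                "costs.mri_exam", "costs.clp_contrast")) {
    z <- override_parameter(z, pth, 0, revalidate = FALSE)
  }
  expect_equal(test_cost(z, "mri_clp"), 0)
})

test_that("productivity loss values volunteering hours at printed wages", {
  p <- bc_primary()
  base <- (63.8 * 7.7 + 36 * 7.9) * 0.7
  expect_equal(productivity_cost("MODERATE", p), base)
  expect_equal(productivity_cost("SEVERE", p), base)
  expect_equal(productivity_cost("MILD", p), 0.6 * base)
  expect_equal(productivity_cost("NO_AD", p), 0)
  expect_equal(productivity_cost("EARLY", p), 0)
  expect_equal(base, 542.962)  # printed-value arithmetic
})

test_that("state cycle costs assemble care, drug and follow-up components", {
  p <- bc_primary()
  expect_equal(cycle_cost("DEAD", p), 0)
  b <- cycle_cost("MILD|HOME|UNDETECTED", p, breakdown = TRUE)
  expect_equal(b[["followup"]], 0)
  expect_equal(b[["drug"]], 0)
  expect_equal(b[["care"]],
               param_get(p, "costs.home_basic_costs.mild") + 1034 * 8.4 +
                 0.35 * param_get(p, "costs.caregiver_health_cost_per_cycle"))
  b2 <- cycle_cost("SEVERE|INSTITUTION|TREATED_STD", p, breakdown = TRUE)
  expect_equal(b2[["care"]],
               param_get(p, "costs.institution_hostel") + 1034 * 13)
  expect_equal(b2[["drug"]], 286)  # memantine at severe stage
  expect_equal(b2[["followup"]], 41)
  b3 <- cycle_cost("MODERATE|HOME|TREATED_STD", p, breakdown = TRUE)
  expect_equal(b3[["drug"]], 572)  # donepezil at mild/moderate
  # false positives: follow-up and drug, but no care or productivity cost
  b4 <- cycle_cost("NO_AD|HOME|FP_TREATED", p, breakdown = TRUE)
  expect_equal(unname(b4[c("care", "productivity")]), c(0, 0))
  expect_equal(b4[["drug"]], 572)
  b5 <- cycle_cost("NO_AD|HOME|FP_TREATED", p, treatment_T_enabled = TRUE,
                   breakdown = TRUE)
  expect_equal(b5[["drug"]], 500)
})

test_that("cycle cost is additive: zeroing a component removes its contribution", {
  p <- bc_primary()
  state <- "MODERATE|HOME|TREATED_STD"
  full <- cycle_cost(state, p)
  q <- override_parameter(p, "costs.donepezil_per_cycle", 0, revalidate = FALSE)
  expect_equal(full - cycle_cost(state, q), 572)
  q2 <- override_parameter(p, "costs.followup_consult", 0, revalidate = FALSE)
  expect_equal(full - cycle_cost(state, q2), 41)
})

test_that("discounting follows the half-year compounding rule", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_equal(discount_factor(2, 0.05), 1 / 1.05)
  expect_equal(discount_factor(4, 0.05), 1 / 1.05^2)
})

test_that("reward accumulation matches hand-computed single-cycle values", {
  p <- override_parameter(bc_primary(), "econ.annual_discount_rate", 0)
  s <- scenario_spec("PRIMARY")
  states <- state_space(s)
  occ <- matrix(0, 1, length(states), dimnames = list(NULL, states))
  occ[1, "NO_AD|HOME|UNDETECTED"] <- 1
  tr <- list(occupancy = occ, event_costs = 0)
  out <- accumulate(tr, p)
  expect_equal(out$qaly, 0.5 * 0.826)
  expect_equal(out$cost, 0)
})

test_that("discounting never increases totals and QALYs respect the ceiling", {
  res <- run_primary()
  p <- bc_primary()
  p0 <- override_parameter(p, "econ.annual_discount_rate", 0)
  p2 <- override_parameter(p, "econ.annual_discount_rate", 0.10)
  for (tr in res$traces) {
    a0 <- accumulate(tr, p0)
    a1 <- accumulate(tr, p)
    a2 <- accumulate(tr, p2)
    expect_lte(a1$cost, a0$cost)
    expect_lte(a1$qaly, a0$qaly)
    expect_lte(a2$cost, a1$cost)
    expect_lte(a2$qaly, a1$qaly)
    expect_lte(a0$qaly, 0.5 * nrow(tr$occupancy) * 0.826)
  }
})
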