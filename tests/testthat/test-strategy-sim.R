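test_that("initial cohort composition follows printed prevalences", {
  p <- bc_primary()
  d <- initial_distribution(p, scenario_spec("PRIMARY"))
  expect_equal(d[["MILD"]], 0.56 * 0.559)
  expect_equal(d[["MODERATE"]], 0.56 * 0.399)
  expect_equal(d[["SEVERE"]], 0.56 * 0.042)
  expect_equal(d[["NO_AD"]], 0.44)
  expect_equal(sum(d), 1)

  ds <- initial_distribution(bc_screen(), scenario_spec("SCREEN_ALL"))
  expect_equal(sum(ds[c("EARLY", "MILD", "MODERATE", "SEVERE")]), 0.01)
  expect_equal(ds[["EARLY"]] / ds[["MILD"]], 8 / 7)
  expect_equal(ds[["MODERATE"]] / ds[["MILD"]], 0.399 / 0.559)
  expect_equal(ds[["EARLY"]], 0.0038987, tolerance = 2e-4)

  p0 <- override_parameter(bc_screen(), "epidemiology.screen_prevalence", 0,
                           revalidate = FALSE)
  d0 <- initial_distribution(p0, scenario_spec("SCREEN_ALL"))
  expect_equal(d0[["NO_AD"]], 1)
})

test_that("screening schedules land on the rescreening grid", {
  p <- bc_screen()
  s <- scenario_spec("SCREEN_ALL")
  expect_equal(schedule_screens(s, p), c(0, 10, 20))
  p1 <- override_parameter(p, "econ.rescreen_interval", 1)
  p1 <- override_parameter(p1, "econ.horizon", 3, revalidate = FALSE)
  expect_equal(schedule_screens(s, p1), c(0, 2, 4))
  p2 <- override_parameter(p, "econ.rescreen_interval", 20)
  expect_equal(schedule_screens(s, p2), 0)
  expect_error(schedule_screens(scenario_spec("PRIMARY"), bc_primary()),
               "tests once")
})

test_that("a zero horizon charges only the initial testing costs", {
  p <- override_parameter(bc_primary(), "econ.horizon", 0, revalidate = FALSE)
  s <- scenario_spec("PRIMARY")
  r <- run_strategy(p, s, "mri_clp")
  sev <- 0.56 * 0.042
  expect_equal(r$outcome$cost, (1 - sev) * test_cost(p, "mri_clp") + sev * 55)
  expect_equal(r$outcome$qaly, 0)
})

test_that("every strategy trace conserves probability mass in both settings", {
  for (res in list(run_primary(), run_screen())) {
    for (tr in res$traces) {
      expect_true(all(abs(rowSums(tr$occupancy) - 1) <= 1e-9))
      expect_true(all(tr$occupancy >= -1e-12))
      expect_true(all(tr$event_costs >= 0))
    }
  }
})

test_that("with neutral treatment, tests relabel but do not change the disease", {
  for (kind in c("PRIMARY", "SCREEN_ALL")) {
    p <- neutralize_treatment(
      if (kind == "PRIMARY") bc_primary() else bc_screen())
    res <- run_scenario(p, scenario_spec(kind))
    totals <- lapply(res$traces, stage_totals)
    for (other in totals[-1]) {
      expect_equal(other, totals[[1]], tolerance = 1e-9)
    }
  }
})

test_that("doubling drug prices raises cost by exactly the discounted drug bill", {
  p <- bc_primary()
  s <- scenario_spec("PRIMARY")
  r <- run_strategy(p, s, "mri")
  doubled <- p
  for (pth in c("costs.donepezil_per_cycle", "costs.memantine_per_cycle",
                "costs.treatment_T_per_cycle")) {
    doubled <- override_parameter(doubled, pth, 2 * param_get(p, pth),
                                  revalidate = FALSE)
  }
  a1 <- accumulate(r$trace, p)
  a2 <- accumulate(r$trace, doubled)
  drug_vec <- vapply(colnames(r$trace$occupancy), function(st)
    cycle_cost(st, p, breakdown = TRUE)[["drug"]], numeric(1))
  df <- discount_factor(seq_len(nrow(r$trace$occupancy)) - 1,
                        p$econ$annual_discount_rate)
  drug_bill <- sum(df * drop(r$trace$occupancy %*% drug_vec))
  expect_equal(a2$cost - a1$cost, drug_bill, tolerance = 1e-9)
  expect_equal(a2$qaly, a1$qaly)
})

test_that("a more accurate test never loses QALYs when treatment helps", {
  p <- bc_primary()
  s <- scenario_spec("PRIMARY")
  base <- run_strategy(p, s, "mri_clp")$outcome$qaly
  better <- override_parameter(p, "tests.mri_clp.sensitivity", 1,
                               revalidate = FALSE)
  worse <- override_parameter(p, "tests.mri_clp.sensitivity", 0.5,
                              revalidate = FALSE)
  expect_gte(run_strategy(better, s, "mri_clp")$outcome$qaly, base)
  expect_lte(run_strategy(worse, s, "mri_clp")$outcome$qaly, base)
})

test_that("ApoE4 screening doubles incident AD relative to population screening", {
  p <- bc_screen()
  m_all <- build_annual_matrix(p, scenario_spec("SCREEN_ALL"), 60)
  m_apo <- build_annual_matrix(bc_apoe4(), scenario_spec("SCREEN_APOE4"), 60)
  # annual rates are doubled before the half-year composition; the common
  # survival factor cancels in the ratio of per-cycle incident flows
  inc_all <- 1 - sqrt(1 - param_get(p, "epidemiology.age_incidence_table.age_60_64"))
  inc_apo <- 1 - sqrt(1 - 2 * param_get(p, "epidemiology.age_incidence_table.age_60_64"))
  h_all <- annual_to_cycle(m_all)
  h_apo <- annual_to_cycle(m_apo)
  from <- "NO_AD|HOME|UNDETECTED"
  early_cols <- grep("^EARLY", colnames(h_all), value = TRUE)
  expect_equal(sum(h_apo[from, early_cols]) / sum(h_all[from, early_cols]),
               inc_apo / inc_all, tolerance = 1e-9)
})
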