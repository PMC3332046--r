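two_state <- matrix(c(0.64, 0.36, 0, 1), 2, byrow = TRUE,
                    dimnames = list(c("MILD|HOME|UNDETECTED", "DEAD"),
                                    c("MILD|HOME|UNDETECTED", "DEAD")))

test_that("cycle conversion takes the principal matrix square root", {
  s <- annual_to_cycle(two_state)
  expect_equal(unname(s), matrix(c(0.8, 0.2, 0, 1), 2, byrow = TRUE),
               tolerance = 1e-10, ignore_attr = TRUE)
  i4 <- diag(4); dimnames(i4) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_equal(unname(annual_to_cycle(i4)), diag(4), ignore_attr = TRUE)
})

test_that("conversion round-trips for base-case and sampled cohort matrices", {
  for (builder in list(
    function() build_annual_matrix(bc_primary(), scenario_spec("PRIMARY"), 70),
    function() build_annual_matrix(bc_screen(), scenario_spec("SCREEN_ALL"), 60),
    function() build_annual_matrix(
      sample_parameter_set(bc_screen(), seed = 11, validate = FALSE),
      scenario_spec("SCREEN_APOE4"), 72))) {
    m <- builder()
    s <- annual_to_cycle(m)
    expect_lt(max(abs(s %*% s - m)), 1e-6)
    expect_equal(unname(rowSums(s)), rep(1, nrow(s)), tolerance = 1e-9)
    expect_true(all(s >= 0))
    expect_equal(unname(s["DEAD", ]),
                 as.numeric(colnames(s) == "DEAD"))  # absorbing row untouched
  }
})

test_that("the iteration agrees with an independent square-root routine", {
  m <- build_annual_matrix(bc_primary(), scenario_spec("PRIMARY"), 70)
  ref <- pracma::sqrtm(unname(m))$B
  expect_lt(max(abs(unname(annual_to_cycle(m)) - ref)), 1e-7)
})

test_that("the scalar drug-improvement parameter expands linearly", {
  expect_equal(unclass(expand_f(0))[1:4],
               list(f_mM = 1, f_MS = 1, f_Mm = 1, f_SM = 1))
  expect_equal(unclass(expand_f(1))[1:4],
               list(f_mM = 0.5, f_MS = 0.5, f_Mm = 2, f_SM = 2))
  expect_equal(unclass(expand_f(0.5))[1:4],
               list(f_mM = 0.75, f_MS = 0.75, f_Mm = 1.5, f_SM = 1.5))
  expect_error(expand_f(1.2), "\\[0, 1\\]")
  expect_error(expand_f(-0.1), "\\[0, 1\\]")
})

test_that("treatment multipliers rescale treated rows and rebalance on the diagonal", {
  p <- bc_screen()
  s <- scenario_spec("SCREEN_ALL")
  m <- build_annual_matrix(p, s, 60)
  expect_equal(apply_treatment(m, treatment_effect()), m)  # neutral

  info_row <- "EARLY|HOME|TREATED_T"
  mild_cols <- grep("^MILD", colnames(m), value = TRUE)
  base_t <- override_parameter(p, "treatment_effect.f_T", 1, revalidate = FALSE)
  m1 <- build_annual_matrix(base_t, s, 60)
  m2 <- apply_treatment(m1, treatment_effect(f_T = 0.5))
  expect_equal(sum(m2[info_row, mild_cols]), 0.5 * sum(m1[info_row, mild_cols]))
  expect_equal(unname(rowSums(m2)), rep(1, nrow(m2)), tolerance = 1e-12)

  mod_mild <- apply_treatment(m1, treatment_effect(f_Mm = 2))
  from <- "MODERATE|HOME|TREATED_STD"
  expect_equal(mod_mild[from, "MILD|HOME|TREATED_STD"],
               2 * m1[from, "MILD|HOME|TREATED_STD"])
  expect_equal(unname(rowSums(mod_mild)), rep(1, nrow(m1)), tolerance = 1e-12)
})

test_that("stepping conserves mass and matches the matrix-product oracle", {
  set.seed(5)
  n <- 5
  m <- matrix(stats::rexp(n * n), n)
  m <- m / rowSums(m)
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  occ <- stats::rexp(n); occ <- occ / sum(occ)
  expect_equal(sum(step_cohort(occ, m)), 1, tolerance = 1e-12)
  expect_equal(step_cohort(step_cohort(occ, m), m),
               drop(occ %*% (m %*% m)), tolerance = 1e-12)
  expect_error(step_cohort(occ[1:3], m), "does not match")
  dead <- c(rep(0, n - 1), 1)
  md <- m; md[n, ] <- 0; md[n, n] <- 1
  expect_equal(step_cohort(dead, md), dead, ignore_attr = TRUE)
})

test_that("cohort traces conserve mass and death accumulates monotonically", {
  for (res in list(run_primary(), run_screen())) {
    for (tr in res$traces) {
      sums <- rowSums(tr$occupancy)
      expect_true(all(abs(sums - 1) <= 1e-9))
      dead <- tr$occupancy[, "DEAD"]
      expect_true(all(diff(dead) >= -1e-12))
    }
  }
})

test_that("treatment lengthens the expected time from mild to severe disease", {
  m <- build_annual_matrix(bc_primary(), scenario_spec("PRIMARY"), 70)
  t_untreated <- expected_time_to_stage(m, "MILD|HOME|UNDETECTED", "SEVERE")
  t_treated_base <- expected_time_to_stage(m, "MILD|HOME|TREATED_STD", "SEVERE")
  m_max <- apply_treatment(m, expand_f(1))
  t_treated_max <- expected_time_to_stage(m_max, "MILD|HOME|TREATED_STD", "SEVERE")
  expect_gte(t_treated_base, t_untreated)
  expect_gte(t_treated_max, t_treated_base)
})

test_that("labelled matrices survive the CSV interchange", {
  m <- build_cycle_matrix(bc_primary(), scenario_spec("PRIMARY"), 70)
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(m, f)
  m2 <- read_matrix_csv(f, period = "CYCLE")
  expect_equal(m2, structure(m, period = "CYCLE"), tolerance = 1e-12)
})
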