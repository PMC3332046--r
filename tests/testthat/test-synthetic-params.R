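test_that("base-case generator reproduces every printed main-text value", {
  p <- bc_primary()
  t_clp <- test_profile(p, "mri_clp")
  expect_equal(t_clp$sens_mild, 0.96)
  expect_equal(t_clp$specificity, 0.87)
  t_mri <- test_profile(p, "mri")
  expect_equal(c(t_mri$sens_early, t_mri$sens_mild, t_mri$sens_moderate,
                 t_mri$specificity), c(0.50, 0.88, 0.95, 0.96))
  t_std <- test_profile(p, "standard")
  expect_equal(t_std$sens_early, 1 - t_std$specificity)
  expect_equal(c(t_std$sens_mild, t_std$specificity), c(0.75, 0.90))
  expect_equal(param_get(p, "epidemiology.primary_stage_split.mild"), 0.559)
  expect_equal(param_get(p, "epidemiology.early_to_mild_ratio"), 8 / 7)
  expect_equal(param_get(bc_screen(), "epidemiology.screen_prevalence"), 0.01)
  expect_equal(param_get(p, "costs.donepezil_per_cycle"), 572)
  expect_equal(param_get(p, "costs.memantine_per_cycle"), 286)
  expect_equal(param_get(p, "costs.treatment_T_per_cycle"), 500)
  expect_equal(param_get(p, "utilities.no_ad"), 0.826)
  expect_equal(param_get(p, "treatment_effect.f_T"), 0.5)
  expect_equal(param_get(p, "epidemiology.apoe4_incidence_multiplier"), 2)
  expect_equal(param_get(p, "econ.horizon"), 3)
  expect_equal(param_get(bc_screen(), "econ.horizon"), 15)
})

test_that("parameter draws are reproducible and respect degenerate ranges", {
  p <- bc_primary()
  a <- sample_parameter_set(p, seed = 42)
  b <- sample_parameter_set(p, seed = 42)
  expect_identical(param_flatten(a), param_flatten(b))
  deg <- list("costs.clp_contrast" = list(low = 250, mode = 250, high = 250))
  d <- sample_parameter_set(p, ranges = deg, seed = 7)
  expect_equal(param_get(d, "costs.clp_contrast"), 250)
})

test_that("sampled sets always pass validation", {
  p <- bc_screen()
  for (seed in 1:5) {
    q <- sample_parameter_set(p, seed = seed, validate = FALSE)
    expect_identical(nrow(validate_parameters(q)), 0L)
  }
})

test_that("redrawn mild share renormalizes the split at a fixed moderate:severe ratio", {
  p <- bc_primary()
  q <- sample_parameter_set(
    p, ranges = list("epidemiology.primary_stage_split.mild" =
                       list(low = 0.50, mode = 0.559, high = 0.75)),
    seed = 3)
  sp <- q$epidemiology$primary_stage_split
  expect_equal(sp$mild + sp$moderate + sp$severe, 1, tolerance = 1e-12)
  expect_equal(sp$moderate / sp$severe, 0.399 / 0.042, tolerance = 1e-9)
})

test_that("triangular draws have the closed-form mean and CDF", {
  set.seed(123)
  x <- rtriangular(10000, 0, 250, 500)
  se <- sqrt((0^2 + 250^2 + 500^2 - 0 * 250 - 0 * 500 - 250 * 500) / 18 / 10000)
  expect_lt(abs(mean(x) - 250), 3 * se)
  ks <- max(abs(stats::ecdf(x)(x) - ptriangular(x, 0, 250, 500)))
  expect_lt(ks, 0.02)
  # asymmetric case against direct numerical checks
  y <- rtriangular(10000, 0.01, 0.01, 0.10)
  expect_true(all(y >= 0.01 & y <= 0.10))
  ks2 <- max(abs(stats::ecdf(y)(y) - ptriangular(y, 0.01, 0.01, 0.10)))
  expect_lt(ks2, 0.02)
})

test_that("distribution sets take explicit printed ranges and default half-widths", {
  p <- bc_primary()
  ds <- make_distribution_set(
    p,
    paths = "costs.donepezil_per_cycle",
    explicit = list("tests.mri_clp.specificity" = c(0.70, 1.00)))
  expect_equal(unlist(ds[["tests.mri_clp.specificity"]]),
               c(low = 0.70, mode = 0.87, high = 1.00))
  expect_equal(unlist(ds[["costs.donepezil_per_cycle"]]),
               c(low = 572 * 0.9, mode = 572, high = 572 * 1.1))
  expect_error(make_distribution_set(p, paths = "no.such.path"), "unknown")
})

test_that("packaged sweep ranges carry the printed endpoints", {
  r <- bc_primary()$psa_ranges
  expect_equal(unlist(r[["costs.clp_contrast"]]),
               c(low = 0, mode = 250, high = 500))
  expect_equal(unlist(r[["tests.mri_clp.specificity"]]),
               c(low = 0.70, mode = 0.87, high = 1.00))
  expect_equal(unlist(r[["tests.mri_clp.sensitivity"]]),
               c(low = 0.90, mode = 0.96, high = 1.00))
  expect_equal(unlist(r[["transitions.speed_multiplier"]]),
               c(low = 0.9, mode = 1.0, high = 1.1))
  rs <- bc_screen()$psa_ranges
  expect_equal(unlist(rs[["costs.treatment_T_per_cycle"]]),
               c(low = 0, mode = 500, high = 1000))
  expect_equal(unlist(rs[["tests.mri.sens_early"]]),
               c(low = 0.10, mode = 0.50, high = 0.50))
})
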