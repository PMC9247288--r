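test_that("grid search matches a brute-force oracle on every scenario", {
  base <- fitness_params()
  for (nm in builtin_scenarios()$name) {
    params <- apply_scenario(base, nm)
    for (obj in c("maternal", "paternal")) {
      got <- suppressWarnings(
        optimize_marriage_age(params, obj, 15, 25, 0.1))
      reg <- builtin_scenarios()
      ov <- reg$overrides[[match(nm, reg$name)]]
      oracle_f <- function(M) {
        oracle_lrf(M, parent = obj,
                   ibi_override = ov$ibi_override,
                   pu_override = ov$pu_override,
                   mortality_multiplier = ov$mortality_multiplier %||% 1,
                   maternal_mortality =
                     isTRUE(ov$maternal_mortality_enabled))
      }
      fine <- brute_force_argmax(oracle_f, 15, 25, 0.01)
      expect_lte(abs(got$optimum_age - fine), 0.1 + 1e-9)
      expect_equal(got$objective_value, oracle_f(got$optimum_age),
                   tolerance = 1e-12)
    }
  }
})

test_that("refining the step never decreases the found objective", {
  params <- apply_scenario(fitness_params(), "contraception")
  vals <- vapply(c(1, 0.5, 0.1, 0.05, 0.01), function(s) {
    optimize_marriage_age(params, "maternal", 15, 25, s)$objective_value
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("ties break toward the lowest age and boundaries warn", {
  # zero paternity uncertainty makes both objectives identical
  p0 <- fitness_params(pu_override = 0)
  m <- optimize_marriage_age(p0, "maternal")
  f <- optimize_marriage_age(p0, "paternal")
  expect_identical(m$optimum_age, f$optimum_age)
  # a flat objective (TF = 0 everywhere) returns the grid's first age
  flat <- optimize_marriage_age(fitness_params(), "maternal",
                                age_min = 34, age_max = 34.5, step = 0.1) |>
    suppressWarnings()
  expect_equal(flat$optimum_age, 34)
  expect_warning(
    optimize_marriage_age(fitness_params(), "maternal", 18, 25, 0.1),
    "boundary")
  expect_error(optimize_marriage_age(fitness_params(), "maternal",
                                     20, 15, 0.1), "age_min")
  expect_error(optimize_marriage_age(fitness_params(), "maternal",
                                     15, 25, 0), "step")
})

test_that("optimum ages land near the reported scenario optima", {
  base <- fitness_params()
  reported <- list(basic = c(17.6, 16.4),
                   contraception = c(20.1, 18.2),
                   monitoring_with_support = c(20.2, 20.2))
  for (nm in names(reported)) {
    params <- apply_scenario(base, nm)
    m <- optimize_marriage_age(params, "maternal")$optimum_age
    f <- optimize_marriage_age(params, "paternal")$optimum_age
    expect_lte(abs(m - reported[[nm]][1]), 0.5)
    expect_lte(abs(f - reported[[nm]][2]), 0.5)
  }
})

test_that("the conflict table has one ordered row per scenario with exact deltas", {
  tab <- suppressWarnings(conflict_table("all"))
  expect_s3_class(tab, "mf_conflict")
  expect_equal(tab$scenario, builtin_scenarios()$name)
  expect_equal(tab$delta_age, tab$paternal_opt_age - tab$maternal_opt_age)
  expect_equal(tab$delta_lrf, tab$paternal_lrf - tab$maternal_lrf)
  expect_equal(tab$delta_mortality,
               tab$mortality_at_paternal_opt - tab$mortality_at_maternal_opt)
  expect_equal(tab$delta_stunting,
               tab$stunting_at_paternal_opt - tab$stunting_at_maternal_opt)
  # fixed-PU scenarios: no conflict over marriage age
  fixed_pu <- c("education", "monitoring_with_support",
                "monitoring_without_support")
  expect_equal(tab$delta_age[tab$scenario %in% fixed_pu], rep(0, 3))
  # ramp-PU scenarios: the father's optimum is never later than the mother's
  expect_true(all(tab$delta_age[!tab$scenario %in% fixed_pu] <= 0))
})

test_that("the at-ages validation mode reproduces reported basic-row rates", {
  tab <- conflict_table("basic", at_ages = c(17.6, 16.4))
  expect_equal(tab$maternal_opt_age, 17.6)
  expect_equal(round(100 * tab$stunting_at_maternal_opt, 1), 48.0)
  expect_equal(round(100 * tab$stunting_at_paternal_opt, 1), 57.0)
  expect_equal(round(100 * tab$mortality_at_maternal_opt, 1), 34.0)
  expect_equal(round(100 * tab$mortality_at_paternal_opt, 1), 46.3)
  expect_equal(round(tab$maternal_lrf, 1), 4.1)
  expect_error(conflict_table("basic", at_ages = c(17.6, NA)), "at_ages")
})

test_that("sweeps evaluate every grid point without touching the input", {
  params <- fitness_params()
  curve <- sweep_ages(params, 15, 20, 1)
  expect_equal(nrow(curve), 6L)
  expect_equal(curve$marriage_age, 15:20)
  expect_equal(curve$total_fertility[c(1, 6)], c(9.5, 14 / 3.25))
  expect_equal(curve$ibi[6], 3.25)
  expect_equal(curve$paternity_uncertainty[6], 0.25)
  expect_true(all(diff(curve$child_mortality_rate) <= 0))
  expect_null(params$ibi_override) # params untouched
  dense <- sweep_ages(fitness_params(), 15, 25, 0.1)
  expect_equal(nrow(dense), 101L)
  expect_true(all(diff(dense$marriage_age) > 0))
})
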