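p <- fitness_params()

test_that("inter-birth interval follows the 2-to-3.25 ramp and overrides", {
  expect_equal(inter_birth_interval(15, p), 2.0)
  expect_equal(inter_birth_interval(20, p), 3.25)
  p_ov <- fitness_params(ibi_override = 3)
  expect_equal(inter_birth_interval(17, p_ov), 3.0)
  expect_equal(inter_birth_interval(c(15, 18, 21), p_ov), c(3, 3, 3))
  expect_error(inter_birth_interval(NaN, p), "finite")
  expect_error(inter_birth_interval(Inf, p), "finite")
})

test_that("age at first pregnancy is marriage age plus the lag", {
  expect_equal(age_first_pregnancy(15, p), 16)
  expect_equal(age_first_pregnancy(17.6, p), 18.6)
  expect_equal(age_first_pregnancy(34, p), 34 + 1)
})

test_that("total fertility matches the span-over-interval formula", {
  expect_equal(total_fertility(15, p), 9.5)
  expect_equal(total_fertility(16.4, p), 17.6 / 2.35) # 7.489, prints 7.5
  expect_equal(total_fertility(17.6, p), 16.4 / 2.65) # 6.189, prints 6.2
  expect_equal(total_fertility(34, p), 0) # AFP reaches the cessation age
  expect_equal(total_fertility(34.5, p), 0) # floored, not negative
})

test_that("low-birth-weight risk ramps from 0.9 down and clips at zero", {
  expect_equal(lbw_risk(15, p), 0.9)
  expect_equal(lbw_risk(20, p), 0.4)
  expect_equal(lbw_risk(24, p), 0)
  expect_equal(lbw_risk(30, p), 0)
})

test_that("child mortality composes LBW, the postnatal factor and multiplier", {
  # basic model at the two reported optima
  expect_equal(child_mortality_rate(17.6, p), 0.64 * (0.7 - 2.6 * 0.065))
  expect_equal(round(100 * child_mortality_rate(17.6, p), 1), 34.0)
  expect_equal(round(100 * child_mortality_rate(16.4, p), 1), 46.3)
  # scaled variant, direct arithmetic
  p_ph <- fitness_params(mortality_multiplier = 0.9)
  expect_equal(child_mortality_rate(16.7, p_ph), 0.73 * 0.5895 * 0.9)
  expect_error(fitness_params(mortality_multiplier = -0.1), "non-negative")
})

test_that("stunting is LBW times catch-up times the scenario multiplier", {
  expect_equal(stunting_rate(17.6, p), 0.48)
  expect_equal(stunting_rate(16.4, p), 0.57)
  p3 <- fitness_params(stunting_multiplier = 3)
  expect_equal(stunting_rate(22.1, p3), 0.19 * 0.75 * 3) # 0.4275, prints 42.8
  expect_equal(stunting_rate(15, p3), 1) # 2.025 pre-clip, capped at 1
})

test_that("paternity uncertainty ramps 0 to 0.25 and honors the override", {
  expect_equal(paternity_uncertainty(15, p), 0)
  expect_equal(paternity_uncertainty(20, p), 0.25)
  p_mon <- fitness_params(pu_override = 0.01)
  expect_equal(paternity_uncertainty(c(15, 19, 24), p_mon), rep(0.01, 3))
})

test_that("maternal mortality risk is the cubic when enabled, else zero", {
  expect_equal(maternal_mortality_risk(17, p), 0)
  p_mm <- fitness_params(maternal_mortality_enabled = TRUE)
  expect_equal(maternal_mortality_risk(15, p_mm),
               0.485 - 0.033 * 15 + 0.000023 * 15^3) # 0.067625
  expect_equal(maternal_mortality_risk(20, p_mm),
               0.485 - 0.033 * 20 + 0.000023 * 20^3) # 0.009
})

test_that("parental fitness values reproduce the reported scenario cells", {
  expect_equal(maternal_lrf(17.6, p), (16.4 / 2.65) * (1 - 0.33984))
  expect_equal(round(maternal_lrf(17.6, p), 1), 4.1)
  p_mws <- fitness_params(ibi_override = 2, pu_override = 0.01)
  expect_equal(maternal_lrf(20.2, p_mws), 6.9 * (1 - 0.13756))
  expect_equal(round(maternal_lrf(20.2, p_mws), 1), 6.0)
  expect_equal(paternal_lrf(20.2, p_mws), 6.9 * (1 - 0.13756) * 0.99)
  expect_equal(round(paternal_lrf(20.2, p_mws), 1), 5.9)
  p_c <- fitness_params(ibi_override = 3)
  expect_equal(paternal_lrf(18.2, p_c),
               (15.8 / 3) * (1 - 0.28536) * (1 - 0.16))
  expect_equal(round(paternal_lrf(18.2, p_c), 1), 3.2)
  expect_equal(maternal_lrf(34, p), 0)
})

test_that("fitness_at composes field-by-field with the single operations", {
  ages <- c(15, 16.4, 17.6, 20.1, 22.1, 30)
  for (params in list(p,
                      fitness_params(ibi_override = 3, pu_override = 0.2,
                                     mortality_multiplier = 0.9),
                      fitness_params(maternal_mortality_enabled = TRUE))) {
    out <- fitness_at(ages, params)
    expect_equal(out$marriage_age, ages)
    expect_equal(out$afp, age_first_pregnancy(ages, params))
    expect_equal(out$ibi, inter_birth_interval(ages, params))
    expect_equal(out$total_fertility, total_fertility(ages, params))
    expect_equal(out$lbw_risk, lbw_risk(ages, params))
    expect_equal(out$postnatal_factor, postnatal_factor(ages, params))
    expect_equal(out$child_mortality_rate, child_mortality_rate(ages, params))
    expect_equal(out$stunting_rate, stunting_rate(ages, params))
    expect_equal(out$paternity_uncertainty,
                 paternity_uncertainty(ages, params))
    expect_equal(out$maternal_mortality_risk,
                 maternal_mortality_risk(ages, params))
    expect_equal(out$maternal_lrf, maternal_lrf(ages, params))
    expect_equal(out$paternal_lrf, paternal_lrf(ages, params))
  }
})

test_that("parameter invariants are enforced at construction", {
  expect_error(fitness_params(reproductive_end_age = 16),
               "reproductive_end_age")
  expect_error(fitness_params(ibi_intercept = 0), "ibi_intercept")
  expect_error(fitness_params(ibi_override = -1), "ibi_override")
  expect_error(fitness_params(lbw_slope = NA), "finite")
  expect_error(fitness_params(maternal_mortality_enabled = NA),
               "TRUE or FALSE")
  expect_s3_class(fitness_params(), "mf_params")
})
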