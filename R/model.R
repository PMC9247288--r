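#' @keywords internal
#' @noRd
clip01 <- function(x) pmin(pmax(x, 0), 1)

#' @keywords internal
#' @noRd
check_age <- function(age) {
  if (!is.numeric(age) || length(age) == 0L || any(!is.finite(age))) {
    stop("marriage age must be finite and numeric", call. = FALSE)
  }
  invisible(age)
}

#' @keywords internal
#' @noRd
check_params <- function(params) {
  if (!inherits(params, "mf_params")) {
    stop("`params` must be created by fitness_params()", call. = FALSE)
  }
  invisible(params)
}

#' Inter-birth interval
#'
#' Years between successive births at a given marriage age. Rises linearly
#' from 2 years for marriage at 15 to 3.25 years at 20, reflecting growing
#' maternal autonomy (contraceptive access) with later marriage, unless a
#' scenario fixes it via `ibi_override`.
#'
#' @param age Marriage age `M` in years (vectorized).
#' @param params An [fitness_params()] object.
#' @return Inter-birth interval(s) in years.
#' @examples
#' inter_birth_interval(c(15, 20), fitness_params())
#' @export
inter_birth_interval <- function(age, params = fitness_params()) {
  check_age(age)
  check_params(params)
  ibi <- if (!is.null(params$ibi_override)) {
    rep(params$ibi_override, length(age))
  } else {
    params$ibi_intercept + (age - params$reference_age) * params$ibi_slope
  }
  if (any(ibi <= 0)) {
    stop("inter-birth interval must be positive; got ", min(ibi),
         " (marriage age outside the model's domain)", call. = FALSE)
  }
  ibi
}

#' Age at first pregnancy
#'
#' Marriage age plus the first-birth lag (1 year by default).
#'
#' @inheritParams inter_birth_interval
#' @return Age(s) at first pregnancy in years.
#' @export
age_first_pregnancy <- function(age, params = fitness_params()) {
  check_age(age)
  check_params(params)
  age + params$first_birth_lag
}

#' Total fertility
#'
#' Continuous offspring count: the reproductive span from age at first
#' pregnancy to the end of reproduction (35 years), divided by the
#' inter-birth interval, floored at 0. Not rounded: the model treats
#' fertility as a rate, and reported values like 9.5 or 7.5 offspring are
#' meaningful.
#'
#' @inheritParams inter_birth_interval
#' @return Offspring count(s), continuous and non-negative.
#' @examples
#' total_fertility(15, fitness_params()) # 9.5
#' @export
total_fertility <- function(age, params = fitness_params()) {
  afp <- age_first_pregnancy(age, params)
  ibi <- inter_birth_interval(age, params)
  pmax(0, (params$reproductive_end_age - afp) / ibi)
}

#' Low-birth-weight risk
#'
#' Probability that an offspring is born with low birth weight, declining
#' linearly from 0.9 for marriage at 15 years to 0.4 at 20 years (maternal
#' capital accretes with age), clipped to \[0, 1\].
#'
#' @inheritParams inter_birth_interval
#' @return Probability(ies) in \[0, 1\].
#' @export
lbw_risk <- function(age, params = fitness_params()) {
  check_age(age)
  check_params(params)
  clip01(params$lbw_intercept -
           (age - params$reference_age) * params$lbw_slope)
}

#' Post-natal survival factor
#'
#' The factor multiplying low-birth-weight risk in the child mortality rate:
#' `postnatal_intercept - postnatal_slope * (M - reference_age)`, floored at
#' 0. It captures the declining post-natal mortality of children of
#' later-marrying mothers.
#'
#' @inheritParams inter_birth_interval
#' @return Non-negative factor(s).
#' @export
postnatal_factor <- function(age, params = fitness_params()) {
  check_age(age)
  check_params(params)
  pmax(0, params$postnatal_intercept -
         (age - params$reference_age) * params$postnatal_slope)
}

#' Child mortality rate
#'
#' Fraction of births dying before age 5: low-birth-weight risk times the
#' post-natal factor, scaled by `mortality_multiplier` (0.9 under the
#' public-health intervention, 1.2 under an economic shock), clipped to
#' \[0, 1\].
#'
#' @inheritParams inter_birth_interval
#' @return Probability(ies) in \[0, 1\].
#' @examples
#' child_mortality_rate(17.6, fitness_params()) # 0.340
#' @export
child_mortality_rate <- function(age, params = fitness_params()) {
  lbw <- lbw_risk(age, params)
  clip01(lbw * postnatal_factor(age, params) * params$mortality_multiplier)
}

#' Stunting rate
#'
#' Prevalence of impaired linear growth among offspring: low-birth-weight
#' risk times the catch-up factor (0.75: a quarter of low-birth-weight
#' children catch up postnatally), scaled by `stunting_multiplier` (3 when
#' the marital household suppresses maternal autonomy without compensatory
#' childcare), clipped to \[0, 1\].
#'
#' @inheritParams inter_birth_interval
#' @return Probability(ies) in \[0, 1\].
#' @export
stunting_rate <- function(age, params = fitness_params()) {
  lbw <- lbw_risk(age, params)
  clip01(lbw * params$stunting_catchup_factor * params$stunting_multiplier)
}

#' Paternity uncertainty
#'
#' Fraction of a wife's offspring not sired by the husband. Rises linearly
#' with marriage age (0 at 15 years to 0.25 at 20), reflecting greater female
#' autonomy with later marriage, unless a scenario fixes it via
#' `pu_override` (0.01 under household monitoring, 0.2 under the education
#' scenario). Clipped to \[0, 1\].
#'
#' @inheritParams inter_birth_interval
#' @return Fraction(s) in \[0, 1\].
#' @export
paternity_uncertainty <- function(age, params = fitness_params()) {
  check_age(age)
  check_params(params)
  pu <- if (!is.null(params$pu_override)) {
    rep(params$pu_override, length(age))
  } else {
    params$pu_slope * (age - params$reference_age)
  }
  clip01(pu)
}

#' Maternal mortality risk
#'
#' Probability that the mother dies over her reproductive career, declining
#' at a decelerating rate with marriage age:
#' `mm_k4 - mm_k5 * M + mm_k6 * M^3`, clipped to \[0, 1\]. Returns 0 unless
#' `maternal_mortality_enabled` is set (the maternal-mortality scenario).
#'
#' @inheritParams inter_birth_interval
#' @return Probability(ies) in \[0, 1\].
#' @export
maternal_mortality_risk <- function(age, params = fitness_params()) {
  check_age(age)
  check_params(params)
  if (!params$maternal_mortality_enabled) {
    return(rep(0, length(age)))
  }
  clip01(params$mm_k4 - params$mm_k5 * age + params$mm_k6 * age^3)
}

#' Maternal lifetime reproductive fitness
#'
#' Expected number of offspring surviving to age 5:
#' `TF * (1 - MR)`, additionally discounted by `(1 - MMR)` when maternal
#' mortality is enabled.
#'
#' @inheritParams inter_birth_interval
#' @return Surviving offspring count(s).
#' @examples
#' maternal_lrf(17.6, fitness_params()) # ~4.09, prints as 4.1
#' @export
maternal_lrf <- function(age, params = fitness_params()) {
  total_fertility(age, params) *
    (1 - child_mortality_rate(age, params)) *
    (1 - maternal_mortality_risk(age, params))
}

#' Paternal lifetime reproductive fitness
#'
#' The husband's surviving genetic offspring: maternal fitness discounted by
#' paternity uncertainty, `maternal_lrf * (1 - PU)`. Fathers do not remarry
#' on the wife's death, so the maternal-mortality discount carries through.
#'
#' @inheritParams inter_birth_interval
#' @return Surviving offspring count(s).
#' @export
paternal_lrf <- function(age, params = fitness_params()) {
  maternal_lrf(age, params) * (1 - paternity_uncertainty(age, params))
}

#' Evaluate the full model at given marriage ages
#'
#' Computes every intermediate and final quantity of the fitness model at each
#' marriage age, one row per age. This is the workhorse behind
#' [sweep_ages()] and [conflict_table()].
#'
#' @param age Marriage age(s) `M` in years.
#' @param params An [fitness_params()] object.
#' @return A tibble with one row per age and columns `marriage_age`, `afp`,
#'   `ibi`, `total_fertility`, `lbw_risk`, `postnatal_factor`,
#'   `child_mortality_rate`, `stunting_rate`, `paternity_uncertainty`,
#'   `maternal_mortality_risk`, `maternal_lrf`, `paternal_lrf`.
#' @examples
#' fitness_at(c(15, 17.6, 20), fitness_params())
#' @export
fitness_at <- function(age, params = fitness_params()) {
  check_age(age)
  check_params(params)
  tibble::tibble(
    marriage_age = age,
    afp = age_first_pregnancy(age, params),
    ibi = inter_birth_interval(age, params),
    total_fertility = total_fertility(age, params),
    lbw_risk = lbw_risk(age, params),
    postnatal_factor = postnatal_factor(age, params),
    child_mortality_rate = child_mortality_rate(age, params),
    stunting_rate = stunting_rate(age, params),
    paternity_uncertainty = paternity_uncertainty(age, params),
    maternal_mortality_risk = maternal_mortality_risk(age, params),
    maternal_lrf = maternal_lrf(age, params),
    paternal_lrf = paternal_lrf(age, params)
  )
}
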