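#' Model parameters
#'
#' Constructs the full parameter set of the marriage-age fitness model. Every
#' quantity in the model is a closed-form function of the woman's age at
#' marriage `M`; the parameters below are the constants, ramps and switches of
#' those functions. Defaults reproduce the basic model; scenarios override
#' individual fields (see [builtin_scenarios()]).
#'
#' All linear ramps are anchored at `reference_age` (15 years) and continue
#' linearly outside the 15--20 year range they were calibrated on; derived
#' probabilities are clipped to \[0, 1\] and the post-natal survival factor is
#' floored at 0.
#'
#' @param reproductive_end_age Age (years) at which reproduction ceases.
#' @param reference_age Anchor age (years) of all linear ramps.
#' @param first_birth_lag Years from marriage to first pregnancy, so
#'   `AFP = M + first_birth_lag`.
#' @param ibi_intercept,ibi_slope Inter-birth interval (years) at the
#'   reference age and its increase per year of marriage age:
#'   `IBI = ibi_intercept + ibi_slope * (M - reference_age)`.
#' @param ibi_override Optional fixed inter-birth interval (years); when set it
#'   replaces the ramp entirely (contraception and monitoring scenarios).
#' @param lbw_intercept,lbw_slope Low-birth-weight probability at the reference
#'   age and its decrease per year: `LBW = lbw_intercept - lbw_slope * (M -
#'   reference_age)`, clipped to \[0, 1\].
#' @param postnatal_intercept,postnatal_slope Post-natal mortality factor at
#'   the reference age and its decrease per year of marriage age; the factor
#'   `postnatal_intercept - postnatal_slope * (M - reference_age)` is floored
#'   at 0 and multiplies LBW to give the child mortality rate.
#' @param mortality_multiplier Multiplicative scaling of the full child
#'   mortality rate (public-health intervention 0.9, economic shock 1.2).
#' @param stunting_catchup_factor Fraction of low-birth-weight children that
#'   remain stunted after postnatal catch-up growth.
#' @param stunting_multiplier Multiplicative scaling of the stunting rate
#'   (3 in the monitoring-without-support scenario).
#' @param pu_slope Increase in paternity uncertainty per year of marriage age.
#' @param pu_override Optional fixed paternity uncertainty replacing the ramp.
#' @param maternal_mortality_enabled Include the maternal mortality risk term
#'   in maternal fitness?
#' @param mm_k4,mm_k5,mm_k6 Constants of the maternal mortality risk cubic
#'   `MMR = mm_k4 - mm_k5 * M + mm_k6 * M^3`.
#'
#' @return An object of class `mf_params`: a validated named list.
#' @examples
#' p <- fitness_params()
#' total_fertility(15, p) # 9.5 offspring for marriage at 15
#' @seealso [fitness_at()], [apply_scenario()]
#' @export
fitness_params <- function(reproductive_end_age = 35,
                           reference_age = 15,
                           first_birth_lag = 1,
                           ibi_intercept = 2.0,
                           ibi_slope = 0.25,
                           ibi_override = NULL,
                           lbw_intercept = 0.9,
                           lbw_slope = 0.1,
                           postnatal_intercept = 0.7,
                           postnatal_slope = 0.065,
                           mortality_multiplier = 1.0,
                           stunting_catchup_factor = 0.75,
                           stunting_multiplier = 1.0,
                           pu_slope = 0.05,
                           pu_override = NULL,
                           maternal_mortality_enabled = FALSE,
                           mm_k4 = 0.485,
                           mm_k5 = 0.033,
                           mm_k6 = 0.000023) {
  params <- list(
    reproductive_end_age = reproductive_end_age,
    reference_age = reference_age,
    first_birth_lag = first_birth_lag,
    ibi_intercept = ibi_intercept,
    ibi_slope = ibi_slope,
    ibi_override = ibi_override,
    lbw_intercept = lbw_intercept,
    lbw_slope = lbw_slope,
    postnatal_intercept = postnatal_intercept,
    postnatal_slope = postnatal_slope,
    mortality_multiplier = mortality_multiplier,
    stunting_catchup_factor = stunting_catchup_factor,
    stunting_multiplier = stunting_multiplier,
    pu_slope = pu_slope,
    pu_override = pu_override,
    maternal_mortality_enabled = maternal_mortality_enabled,
    mm_k4 = mm_k4,
    mm_k5 = mm_k5,
    mm_k6 = mm_k6
  )
  validate_params(params)
}

#' @keywords internal
#' @noRd
validate_params <- function(params) {
  numeric_fields <- setdiff(names(params),
                            c("ibi_override", "pu_override",
                              "maternal_mortality_enabled"))
  for (f in numeric_fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter `", f, "` must be a single finite number", call. = FALSE)
    }
  }
  for (f in c("ibi_override", "pu_override")) {
    v <- params[[f]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || !is.finite(v))) {
      stop("parameter `", f, "` must be NULL or a single finite number",
           call. = FALSE)
    }
  }
  if (!is.logical(params$maternal_mortality_enabled) ||
      length(params$maternal_mortality_enabled) != 1L ||
      is.na(params$maternal_mortality_enabled)) {
    stop("parameter `maternal_mortality_enabled` must be TRUE or FALSE",
         call. = FALSE)
  }
  if (params$reproductive_end_age <=
      params$reference_age + params$first_birth_lag) {
    stop("`reproductive_end_age` must exceed `reference_age + first_birth_lag`",
         call. = FALSE)
  }
  if (params$ibi_intercept <= 0) {
    stop("`ibi_intercept` must be positive", call. = FALSE)
  }
  if (!is.null(params$ibi_override) && params$ibi_override <= 0) {
    stop("`ibi_override`, when set, must be positive", call. = FALSE)
  }
  if (params$mortality_multiplier < 0) {
    stop("`mortality_multiplier` must be non-negative", call. = FALSE)
  }
  structure(params, class = "mf_params")
}

#' @export
print.mf_params <- function(x, ...) {
  cat("<mf_params> marriage-age fitness model parameters\n")
  shown <- vapply(x, function(v) {
    if (is.null(v)) "ramp (no override)" else format(v)
  }, character(1))
  cat(paste0("  ", format(names(shown)), " : ", shown, collapse = "\n"), "\n")
  invisible(x)
}

#' Names of overridable model parameters
#'
#' The set of field names that scenario overrides may target.
#'
#' @return A character vector of parameter names.
#' @export
param_fields <- function() {
  names(fitness_params())
}
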