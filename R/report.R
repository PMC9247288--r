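#' Render a conflict table for reporting
#'
#' Converts a [conflict_table()] result to the reporting scale: rates become
#' percentages on 0--100, and (in rounded mode) ages/fitness are rounded to
#' `digits_age` decimals and percentages to `digits_pct`. Internally the
#' package always keeps probabilities on \[0, 1\]; scaling and rounding
#' happen only here.
#'
#' @param x An `mf_conflict` tibble.
#' @param digits_age Decimals for ages and fitness (default 1).
#' @param digits_pct Decimals for percentage columns (default 1).
#' @param round Round at all? `FALSE` keeps full precision (used by the CSV
#'   and JSON writers); `TRUE` gives display precision.
#' @return A tibble with columns `scenario`, `maternal_opt_age`,
#'   `paternal_opt_age`, `delta_age`, `maternal_lrf`, `paternal_lrf`,
#'   `delta_lrf`, `maternal_mortality_pct`, `paternal_mortality_pct`,
#'   `delta_mortality_pct`, `maternal_stunting_pct`, `paternal_stunting_pct`,
#'   `delta_stunting_pct`.
#' @export
format_conflict <- function(x, digits_age = 1, digits_pct = 1,
                            round = TRUE) {
  stopifnot(inherits(x, "mf_conflict"))
  if (digits_age < 0 || digits_pct < 0) {
    stop("decimal places must be non-negative", call. = FALSE)
  }
  out <- tibble::tibble(
    scenario = x$scenario,
    maternal_opt_age = x$maternal_opt_age,
    paternal_opt_age = x$paternal_opt_age,
    delta_age = x$delta_age,
    maternal_lrf = x$maternal_lrf,
    paternal_lrf = x$paternal_lrf,
    delta_lrf = x$delta_lrf,
    maternal_mortality_pct = 100 * x$mortality_at_maternal_opt,
    paternal_mortality_pct = 100 * x$mortality_at_paternal_opt,
    delta_mortality_pct = 100 * x$delta_mortality,
    maternal_stunting_pct = 100 * x$stunting_at_maternal_opt,
    paternal_stunting_pct = 100 * x$stunting_at_paternal_opt,
    delta_stunting_pct = 100 * x$delta_stunting
  )
  if (round) {
    age_cols <- c("maternal_opt_age", "paternal_opt_age", "delta_age",
                  "maternal_lrf", "paternal_lrf", "delta_lrf")
    pct_cols <- setdiff(names(out), c("scenario", age_cols))
    out <- dplyr::mutate(
      out,
      dplyr::across(dplyr::all_of(age_cols), ~ round(.x, digits_age)),
      dplyr::across(dplyr::all_of(pct_cols), ~ round(.x, digits_pct))
    )
  }
  out
}

#' Write a conflict table to CSV
#'
#' RFC-4180-style CSV with one header row, percentage columns on the 0--100
#' scale at full precision, deterministic row order (input order).
#'
#' @param x An `mf_conflict` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conflict_csv <- function(x, path) {
  readr::write_csv(format_conflict(x, round = FALSE), path)
  invisible(path)
}

#' Write a marriage-age sweep to CSV
#'
#' One row per grid age with every model quantity, full precision.
#'
#' @param x An `mf_sweep` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(x, path) {
  stopifnot(inherits(x, "mf_sweep"))
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Read a sweep CSV back into an `mf_sweep` tibble
#'
#' Inverse of [write_sweep_csv()]: round-trips the in-memory curve to full
#' double precision.
#'
#' @param path Path to a sweep CSV.
#' @return An `mf_sweep` tibble.
#' @export
read_sweep_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  class(out) <- c("mf_sweep", class(out))
  out
}

# Reference conflict-table values as originally reported for this model.
# Hard-coded reporting-scale numbers (ages/LRF to 1 dp, rates in %);
# discrepancy_note() recomputes the same cells from the equations.
reference_cells <- function() {
  tibble::tribble(
    ~scenario, ~maternal_opt_age, ~paternal_opt_age,
    ~maternal_lrf, ~paternal_lrf,
    ~maternal_mortality_pct, ~paternal_mortality_pct,
    ~maternal_stunting_pct, ~paternal_stunting_pct,
    "basic",                      17.6, 16.4, 4.1, 3.6, 34.0, 46.3, 48.0, 57.0,
    "contraception",              20.1, 18.2, 4.0, 3.2, 14.4, 28.5, 29.2, 43.5,
    "public_health",              16.7, 15.6, 4.4, 4.2, 39.5, 49.7, 54.7, 63.0,
    "economic_shock",             18.4, 17.3, 3.5, 3.0, 35.3, 47.0, 42.0, 50.2,
    "education",                  19.7, 19.7, 4.1, 3.3, 14.0, 14.0, 32.0, 32.0,
    "monitoring_with_support",    20.2, 20.2, 6.0, 5.9, 19.5, 19.5, 28.5, 28.5,
    "monitoring_without_support", 22.1, 22.1, 2.8, 2.8, 52.6, 52.6, 28.5, 28.5,
    "maternal_mortality",         18.4, 17.5, 4.0, 3.6, 34.0, 45.7, 48.0, 57.0
  )
}

#' Reference conflict-table values
#'
#' The conflict-table cell values as originally reported for this model
#' (ages and fitness to 1 decimal, rates as percentages to 1 decimal). Useful
#' for comparing the package's recomputation against the published numbers;
#' see [discrepancy_note()].
#'
#' @return A tibble with one row per built-in scenario.
#' @export
reference_conflict_table <- function() {
  reference_cells()
}

#' Discrepancy note: recomputed vs reference values
#'
#' Several reference cells are not exactly reproducible from the model's own
#' stated equations (rounding and transcription slips in the original
#' presentation; e.g. the public-health mortality cell and the
#' monitoring-without-support stunting cell, whose reported 28.5 conflicts
#' with the 42.8 implied by the threefold stunting penalty). This function
#' evaluates the model at the *reference* optimal ages and tabulates
#' recomputed vs reference values side by side, long format, so the
#' divergent cells are explicit rather than silently "fixed". The equations
#' are always implemented exactly as stated; no cell is adjusted to match.
#'
#' @param params Base parameters (defaults reproduce the reference setup).
#' @return A tibble with columns `scenario`, `quantity`, `reference`,
#'   `recomputed`, `difference` (recomputed − reference), both on the
#'   reporting scale (ages/LRF in natural units, rates in %).
#' @examples
#' note <- discrepancy_note()
#' note[abs(note$difference) > 0.5, ] # the genuinely divergent cells
#' @export
discrepancy_note <- function(params = fitness_params()) {
  ref <- reference_cells()
  at <- purrr::map2(ref$maternal_opt_age, ref$paternal_opt_age, c)
  names(at) <- ref$scenario
  recomputed <- conflict_table(ref$scenario, params, at_ages = at)
  rec <- format_conflict(recomputed, round = FALSE)
  value_cols <- setdiff(names(ref), c("scenario", "maternal_opt_age",
                                      "paternal_opt_age"))
  ref_long <- tidyr::pivot_longer(ref[, c("scenario", value_cols)],
                                  -"scenario", names_to = "quantity",
                                  values_to = "reference")
  rec_long <- tidyr::pivot_longer(rec[, c("scenario", value_cols)],
                                  -"scenario", names_to = "quantity",
                                  values_to = "recomputed")
  out <- dplyr::left_join(ref_long, rec_long,
                          by = c("scenario", "quantity"))
  dplyr::mutate(out, difference = .data$recomputed - .data$reference)
}
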