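#' @keywords internal
#' @noRd
age_grid <- function(age_min, age_max, step) {
  if (!is.finite(age_min) || !is.finite(age_max) || !is.finite(step) ||
      step <= 0 || age_min >= age_max) {
    stop("need age_min < age_max and step > 0", call. = FALSE)
  }
  # integer stepping avoids floating drift on e.g. seq(15, 25, 0.1)
  n <- floor((age_max - age_min) / step + 1e-9)
  age_min + step * (0:n)
}

#' Find the fitness-maximizing marriage age
#'
#' Grid search for the marriage age maximizing maternal or paternal lifetime
#' reproductive fitness over the inclusive grid `age_min, age_min + step,
#' ..., age_max`. Ties (the objective is flat to < 0.01 offspring near its
#' maximum in the basic model) are broken toward the lowest age, making the
#' result deterministic. An optimum on a grid boundary triggers a warning,
#' since it suggests the range truncated the search.
#'
#' @param params An [fitness_params()] object.
#' @param objective `"maternal"` or `"paternal"`: which parent's fitness to
#'   maximize.
#' @param age_min,age_max Search range bounds in years (inclusive).
#' @param step Grid spacing in years.
#' @return An object of class `mf_optimum`: a list with elements `objective`,
#'   `optimum_age`, `objective_value`, `on_boundary` and the grid settings.
#'   Use [generics::tidy()] / [generics::glance()] for tibble views.
#' @examples
#' p <- apply_scenario(fitness_params(), "contraception")
#' optimize_marriage_age(p, "maternal") # optimum near 20.1 years
#' @export
optimize_marriage_age <- function(params,
                                  objective = c("maternal", "paternal"),
                                  age_min = 15, age_max = 25, step = 0.1) {
  check_params(params)
  objective <- match.arg(objective)
  grid <- age_grid(age_min, age_max, step)
  values <- switch(objective,
                   maternal = maternal_lrf(grid, params),
                   paternal = paternal_lrf(grid, params))
  idx <- which.max(values) # first maximum = lowest age on an increasing grid
  on_boundary <- idx == 1L || idx == length(grid)
  if (on_boundary) {
    warning("optimum lies on the search boundary (", grid[idx],
            " y); consider widening [age_min, age_max]", call. = FALSE)
  }
  structure(
    list(objective = objective,
         optimum_age = grid[idx],
         objective_value = values[idx],
         on_boundary = on_boundary,
         age_min = age_min, age_max = age_max, step = step,
         n_grid = length(grid)),
    class = "mf_optimum"
  )
}

#' @export
print.mf_optimum <- function(x, ...) {
  cat("<mf_optimum> ", x$objective, " fitness maximized at marriage age ",
      format(x$optimum_age), " y (LRF ", format(round(x$objective_value, 3)),
      ")\n", sep = "")
  cat("  grid: [", x$age_min, ", ", x$age_max, "] step ", x$step,
      if (x$on_boundary) "  [on boundary]" else "", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an optimizer result
#'
#' @param x An `mf_optimum` object.
#' @param ... Unused.
#' @return A one-row tibble with `objective`, `optimum_age`,
#'   `objective_value`, `on_boundary`.
#' @exportS3Method generics::tidy
tidy.mf_optimum <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    optimum_age = x$optimum_age,
    objective_value = x$objective_value,
    on_boundary = x$on_boundary
  )
}

#' One-row summary of an optimizer run's grid settings
#'
#' @param x An `mf_optimum` object.
#' @param ... Unused.
#' @return A one-row tibble with `age_min`, `age_max`, `step`, `n_grid`.
#' @exportS3Method generics::glance
glance.mf_optimum <- function(x, ...) {
  tibble::tibble(
    age_min = x$age_min, age_max = x$age_max,
    step = x$step, n_grid = x$n_grid
  )
}

#' Parental-conflict table across scenarios
#'
#' For each scenario, finds the maternal- and paternal-optimal marriage ages
#' by grid search, evaluates the model at both optima, and reports fitness,
#' child mortality and stunting at each, plus paternal-minus-maternal
#' differences (the measure of parental conflict). With `at_ages`, skips
#' optimization and evaluates at user-supplied ages instead — a validation
#' mode that separates "reproduce reported rates at reported optima" from
#' "reproduce the optimizer".
#'
#' @param scenarios Scenarios to tabulate: `"all"`, a character vector of
#'   built-in names, or a scenario tibble (see [builtin_scenarios()]).
#' @param params Base parameters each scenario overrides.
#' @param age_min,age_max,step Grid-search settings (see
#'   [optimize_marriage_age()]).
#' @param at_ages Optional fixed evaluation ages instead of optimization:
#'   a length-2 numeric `c(maternal, paternal)` (recycled across scenarios)
#'   or a named list of such pairs keyed by scenario name.
#' @return A tibble of class `mf_conflict`, one row per scenario in input
#'   order, with columns `scenario`, `maternal_opt_age`, `paternal_opt_age`,
#'   `delta_age`, `maternal_lrf`, `paternal_lrf`, `delta_lrf`,
#'   `mortality_at_maternal_opt`, `mortality_at_paternal_opt`,
#'   `delta_mortality`, `stunting_at_maternal_opt`,
#'   `stunting_at_paternal_opt`, `delta_stunting`. Rates are probabilities on
#'   \[0, 1\]; [format_conflict()] renders them as percentages.
#' @examples
#' conflict_table("basic")
#' @export
conflict_table <- function(scenarios = "all", params = fitness_params(),
                           age_min = 15, age_max = 25, step = 0.1,
                           at_ages = NULL) {
  check_params(params)
  specs <- resolve_scenarios(scenarios)
  if (nrow(specs) == 0L) {
    stop("no scenarios selected", call. = FALSE)
  }
  rows <- purrr::pmap(specs, function(name, description, overrides) {
    p <- apply_scenario(params, overrides)
    ages <- tryCatch({
      if (is.null(at_ages)) {
        c(optimize_marriage_age(p, "maternal", age_min, age_max,
                                step)$optimum_age,
          optimize_marriage_age(p, "paternal", age_min, age_max,
                                step)$optimum_age)
      } else {
        pair <- if (is.list(at_ages)) at_ages[[name]] else at_ages
        if (is.null(pair) || length(pair) != 2L || any(!is.finite(pair))) {
          stop("`at_ages` must give a finite c(maternal, paternal) pair",
               call. = FALSE)
        }
        pair
      }
    }, error = function(e) {
      stop("scenario '", name, "': ", conditionMessage(e), call. = FALSE)
    })
    at_m <- fitness_at(ages[1], p)
    at_p <- fitness_at(ages[2], p)
    tibble::tibble(
      scenario = name,
      maternal_opt_age = ages[1],
      paternal_opt_age = ages[2],
      delta_age = ages[2] - ages[1],
      maternal_lrf = at_m$maternal_lrf,
      paternal_lrf = at_p$paternal_lrf,
      delta_lrf = at_p$paternal_lrf - at_m$maternal_lrf,
      mortality_at_maternal_opt = at_m$child_mortality_rate,
      mortality_at_paternal_opt = at_p$child_mortality_rate,
      delta_mortality = at_p$child_mortality_rate - at_m$child_mortality_rate,
      stunting_at_maternal_opt = at_m$stunting_rate,
      stunting_at_paternal_opt = at_p$stunting_rate,
      delta_stunting = at_p$stunting_rate - at_m$stunting_rate
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mf_conflict", class(out))
  attr(out, "grid") <- list(age_min = age_min, age_max = age_max, step = step,
                            at_ages = at_ages)
  out
}

#' Marriage-age sweep
#'
#' Evaluates the full model over an inclusive marriage-age grid, producing
#' the data behind the fertility/mortality/fitness trajectory curves.
#'
#' @param params An [fitness_params()] object (apply a scenario first for
#'   variant curves).
#' @param age_min,age_max,step Grid settings in years.
#' @return A tibble of class `mf_sweep`: one [fitness_at()] row per grid
#'   point, in increasing age order.
#' @examples
#' sweep_ages(fitness_params(), 15, 20, 1)
#' @export
sweep_ages <- function(params = fitness_params(),
                       age_min = 15, age_max = 25, step = 0.1) {
  check_params(params)
  out <- fitness_at(age_grid(age_min, age_max, step), params)
  class(out) <- c("mf_sweep", class(out))
  attr(out, "grid") <- list(age_min = age_min, age_max = age_max, step = step)
  out
}
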