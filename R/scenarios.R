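#' Define a scenario
#'
#' A scenario is a named, declarative set of parameter overrides representing
#' an intervention or shock. Applying it to a base parameter set (see
#' [apply_scenario()]) yields the variant model.
#'
#' @param name Short identifier, e.g. `"contraception"`.
#' @param description Free-text description.
#' @param overrides Named list mapping [fitness_params()] field names to
#'   values. Unknown field names are rejected.
#' @return A one-row tibble with columns `name`, `description` and the
#'   list-column `overrides`.
#' @examples
#' scenario("shock", "economic shock", list(mortality_multiplier = 1.2))
#' @export
scenario <- function(name, description = "", overrides = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("scenario `name` must be a non-empty string", call. = FALSE)
  }
  check_overrides(overrides, name)
  tibble::tibble(
    name = name,
    description = as.character(description),
    overrides = list(overrides)
  )
}

#' @keywords internal
#' @noRd
check_overrides <- function(overrides, scenario_name = NULL) {
  if (!is.list(overrides)) {
    stop("`overrides` must be a named list", call. = FALSE)
  }
  if (length(overrides) > 0L &&
      (is.null(names(overrides)) || any(!nzchar(names(overrides))))) {
    stop("every override must be named", call. = FALSE)
  }
  unknown <- setdiff(names(overrides), param_fields())
  if (length(unknown) > 0L) {
    where <- if (is.null(scenario_name)) "" else
      paste0(" in scenario '", scenario_name, "'")
    stop("unknown parameter field(s)", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(overrides)
}

#' Built-in scenario registry
#'
#' The eight named model variants, in conflict-table row order:
#'
#' \describe{
#'   \item{basic}{No overrides; all ramps active.}
#'   \item{contraception}{Family-planning intervention fixing the
#'     inter-birth interval at 3 years at all marriage ages.}
#'   \item{public_health}{Intervention cutting child mortality by 10\%
#'     (multiplier 0.9) while keeping its association with low birth weight.}
#'   \item{economic_shock}{Economic/environmental shock raising child
#'     mortality by 20\% (multiplier 1.2).}
#'   \item{education}{Women's education: IBI fixed at 3 years (contraceptive
#'     uptake), child mortality cut 10\%, paternity uncertainty raised to a
#'     fixed 0.2 (greater autonomy).}
#'   \item{monitoring_with_support}{Household monitoring of the wife:
#'     infidelity fixed at 0.01 and IBI at 2 years; other household members
#'     compensate for her lost autonomy, so mortality is unchanged.}
#'   \item{monitoring_without_support}{Monitoring without compensatory
#'     childcare: additionally mortality up 20\% and stunting threefold.}
#'   \item{maternal_mortality}{Basic model plus age-declining maternal
#'     mortality risk in maternal fitness.}
#' }
#'
#' @return A tibble of scenarios (columns `name`, `description`,
#'   `overrides`), one row per variant.
#' @examples
#' builtin_scenarios()
#' @export
builtin_scenarios <- function() {
  dplyr::bind_rows(
    scenario("basic",
             "Basic model: all ramps active, no intervention",
             list()),
    scenario("contraception",
             "Family planning fixes the inter-birth interval at 3 years",
             list(ibi_override = 3)),
    scenario("public_health",
             "Public-health intervention reduces child mortality by 10%",
             list(mortality_multiplier = 0.9)),
    scenario("economic_shock",
             "Economic/environmental shock increases child mortality by 20%",
             list(mortality_multiplier = 1.2)),
    scenario("education",
             paste("Women's education: IBI fixed at 3 years, mortality -10%,",
                   "paternity uncertainty fixed at 0.2"),
             list(ibi_override = 3, mortality_multiplier = 0.9,
                  pu_override = 0.2)),
    scenario("monitoring_with_support",
             paste("Household monitoring with compensatory childcare:",
                   "infidelity fixed at 0.01, IBI at 2 years"),
             list(ibi_override = 2, pu_override = 0.01)),
    scenario("monitoring_without_support",
             paste("Household monitoring without compensatory childcare:",
                   "mortality +20%, stunting threefold"),
             list(ibi_override = 2, pu_override = 0.01,
                  mortality_multiplier = 1.2, stunting_multiplier = 3)),
    scenario("maternal_mortality",
             "Basic model with age-declining maternal mortality risk",
             list(maternal_mortality_enabled = TRUE))
  )
}

#' @keywords internal
#' @noRd
resolve_scenarios <- function(spec) {
  if (is.character(spec)) {
    registry <- builtin_scenarios()
    if (identical(spec, "all")) return(registry)
    missing <- setdiff(spec, registry$name)
    if (length(missing) > 0L) {
      stop("unknown scenario(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    return(registry[match(spec, registry$name), ])
  }
  if (is.data.frame(spec)) {
    required <- c("name", "overrides")
    if (!all(required %in% names(spec))) {
      stop("a scenario table needs columns `name` and `overrides`",
           call. = FALSE)
    }
    if (!"description" %in% names(spec)) spec$description <- ""
    purrr::walk2(spec$overrides, spec$name, check_overrides)
    return(tibble::as_tibble(spec[, c("name", "description", "overrides")]))
  }
  stop("scenarios must be given as names or as a scenario table",
       call. = FALSE)
}

#' Apply a scenario to a base parameter set
#'
#' Returns a new [fitness_params()] object in which only the scenario's
#' override fields differ from the base; the base is never modified.
#' Application is idempotent.
#'
#' @param base An [fitness_params()] object.
#' @param spec A scenario: a built-in scenario name, a one-row tibble from
#'   [scenario()] or [builtin_scenarios()], or a bare named list of overrides.
#' @return A new `mf_params` object.
#' @examples
#' apply_scenario(fitness_params(), "contraception")$ibi_override # 3
#' @export
apply_scenario <- function(base, spec) {
  check_params(base)
  overrides <-
    if (is.list(spec) && !is.data.frame(spec)) {
      spec
    } else {
      resolved <- resolve_scenarios(spec)
      if (nrow(resolved) != 1L) {
        stop("`spec` must identify exactly one scenario", call. = FALSE)
      }
      resolved$overrides[[1]]
    }
  check_overrides(overrides)
  params <- unclass(base)
  for (field in names(overrides)) {
    params[[field]] <- overrides[[field]]
  }
  validate_params(params)
}

#' Read scenarios from a JSON config file
#'
#' The config is a UTF-8 JSON array of objects, each with fields `name`,
#' `description` (optional) and `overrides` (object mapping parameter field
#' names to values). Validation is strict: parse failures, duplicate
#' scenario names, unknown object keys and unknown override fields are each
#' distinct errors.
#'
#' @param path Path to the JSON file.
#' @return A scenario tibble, as from [builtin_scenarios()].
#' @seealso [write_scenarios()] for the lossless inverse.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) {
    stop("scenario config not found: ", path, call. = FALSE)
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop("failed to parse scenario config ", path, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (!is.list(parsed)) {
    stop("scenario config must be a JSON array of scenario objects",
         call. = FALSE)
  }
  specs <- purrr::map(parsed, function(obj) {
    extra <- setdiff(names(obj), c("name", "description", "overrides"))
    if (length(extra) > 0L) {
      stop("unknown key(s) in scenario object: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    if (is.null(obj$name)) {
      stop("every scenario object needs a `name`", call. = FALSE)
    }
    scenario(obj$name,
             description = obj$description %||% "",
             overrides = purrr::map(obj$overrides %||% list(), function(v) {
               v <- unlist(v)
               # JSON has no integer/double distinction; parameters are double
               if (is.integer(v)) storage.mode(v) <- "double"
               v
             }))
  })
  specs <- dplyr::bind_rows(specs)
  dup <- unique(specs$name[duplicated(specs$name)])
  if (length(dup) > 0L) {
    stop("duplicate scenario name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  specs
}

#' Write scenarios to a JSON config file
#'
#' Serializes a scenario tibble so that [read_scenarios()] reproduces it
#' exactly (round-trip lossless).
#'
#' @param specs A scenario tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(specs, path) {
  specs <- resolve_scenarios(specs)
  objs <- purrr::pmap(specs, function(name, description, overrides) {
    list(name = name, description = description, overrides = overrides)
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
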