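#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a marriage-age sweep
#'
#' Line charts of total fertility, child mortality rate and both parents'
#' lifetime reproductive fitness against marriage age.
#'
#' @param object An `mf_sweep` tibble from [sweep_ages()].
#' @param ... Unused.
#' @return A ggplot object, facetted by quantity.
#' @exportS3Method ggplot2::autoplot
autoplot.mf_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("marriage_age", "total_fertility",
                                  "child_mortality_rate",
                                  "maternal_lrf", "paternal_lrf")],
    -"marriage_age", names_to = "quantity", values_to = "value"
  )
  long$quantity <- factor(
    long$quantity,
    levels = c("total_fertility", "child_mortality_rate",
               "maternal_lrf", "paternal_lrf"),
    labels = c("Total fertility (offspring)", "Child mortality rate",
               "Maternal LRF (offspring)", "Paternal LRF (offspring)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marriage_age,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Woman's age at marriage (years)", y = NULL,
                  title = "Marriage-age sweep") +
    ggplot2::theme_minimal()
}

#' Plot a parental-conflict table
#'
#' Dumbbell chart of maternal vs paternal optimal marriage ages per
#' scenario; the horizontal gap is the parental conflict over marriage age.
#'
#' @param object An `mf_conflict` tibble from [conflict_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mf_conflict <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$scenario <- factor(d$scenario, levels = rev(d$scenario))
  long <- tidyr::pivot_longer(
    d[, c("scenario", "maternal_opt_age", "paternal_opt_age")],
    -"scenario", names_to = "parent", values_to = "optimum_age"
  )
  long$parent <- ifelse(long$parent == "maternal_opt_age",
                        "Mother", "Father")
  ggplot2::ggplot(d, ggplot2::aes(y = .data$scenario)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$maternal_opt_age,
                                       xend = .data$paternal_opt_age,
                                       yend = .data$scenario),
                          colour = "grey60") +
    ggplot2::geom_point(data = long,
                        ggplot2::aes(x = .data$optimum_age,
                                     colour = .data$parent), size = 3) +
    ggplot2::labs(x = "Optimal age at marriage (years)", y = NULL,
                  colour = NULL,
                  title = "Parental conflict over women's marriage age") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mf_sweep
#' @param x An `mf_sweep` tibble.
#' @export
plot_sweep <- function(x, ...) autoplot.mf_sweep(x, ...)

#' @rdname autoplot.mf_conflict
#' @param x An `mf_conflict` tibble.
#' @export
plot_conflict <- function(x, ...) autoplot.mf_conflict(x, ...)
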