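# ggplot2 displays for the main result types.

#' Plot a life table
#'
#' Survivorship (`lx`, as a proportion of the radix) and remaining life
#' expectancy (`ex`) against age, in two panels.
#'
#' @param object A [build_life_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot life_table
#' @export
autoplot.life_table <- function(object, ...) {
  d <- tibble::tibble(
    age = rep(object$age, 2),
    value = c(object$lx / object$lx[1], object$ex),
    panel = rep(c("survivorship l(x)", "life expectancy e(x)"),
                each = nrow(object))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of hazard ratios
#'
#' @param hr_table Tibble as returned by [tidy()] on an `hr_fit`, or any
#'   table with `level`, `cause`, `hr`, `ci_low`, `ci_high`.
#' @return A ggplot object.
#' @export
plot_hr_forest <- function(hr_table) {
  ggplot2::ggplot(
    hr_table,
    ggplot2::aes(x = .data$hr, y = .data$level)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~cause) +
    ggplot2::labs(x = "hazard ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of life expectancy by lifestyle group
#'
#' @param le_table Result of [life_expectancy_by_group()].
#' @return A ggplot object.
#' @export
plot_life_expectancy <- function(le_table) {
  ggplot2::ggplot(
    le_table,
    ggplot2::aes(x = .data$group, y = .data$ex, fill = .data$sex)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "number of low-risk lifestyle factors",
                  y = "life expectancy (years)") +
    ggplot2::theme_minimal()
}

#' Plot an Arriaga decomposition by age and cause
#'
#' Stacked bars of the per-age, per-cause contributions (years of the
#' life-expectancy gap attributed to each age and cause of death).
#'
#' @param object A [decompose_le_gap()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot le_decomposition
#' @export
autoplot.le_decomposition <- function(object, ...) {
  ggplot2::ggplot(
    object$by_age_cause,
    ggplot2::aes(x = .data$age, y = .data$delta, fill = .data$cause)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "age (years)", y = "contribution to the gap (years)",
      title = sprintf("Decomposition of the %.1f-year gap (%s vs %s, sex %s)",
                      object$gap, object$groups[2], object$groups[1],
                      object$sex)
    ) +
    ggplot2::theme_minimal()
}
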