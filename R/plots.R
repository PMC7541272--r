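# ggplot2 figures for decomposition results

#' Plot a YLL decomposition as grouped contribution bars
#'
#' One bar per component (age structure, death rate, age at death) and
#' approach (partial, total, averaged), in years per 1000 population.
#' Negative bars mean the component reduced the burden.
#'
#' @param object A `yll_decomposition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yll_decomposition <- function(object, ...) {
  d <- tidy(object)
  d <- dplyr::filter(d, .data$component != "residual")
  d$component <- factor(
    .component_label(d$component),
    levels = .component_label(component_names)
  )
  d$approach <- factor(d$approach, levels = c("partial", "total", "averaged"))
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$component, y = .data$estimate, fill = .data$approach)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = NULL,
      y = "Contribution to change in YLL (years per 1000)",
      fill = "Approach",
      title = sprintf(
        "Change in YLL, %s to %s: %.2f years per 1000",
        object$labels[1], object$labels[2], object$delta_yll
      )
    ) +
    ggplot2::theme_minimal()
}

.component_label <- function(x) {
  c(
    age_structure = "Age structure",
    death_rate = "Death rate",
    age_at_death = "Age at death"
  )[x]
}

#' Stepwise death-rate change plot
#'
#' Draws the baseline age-specific death rates, the comparison's rates,
#' and the counterfactual "adjusted baseline" schedule in which every
#' baseline rate is scaled by the same factor so the overall death rate
#' matches the comparison's (see [adjusted_death_rates()]).  The gap
#' between the adjusted curve and the observed comparison curve is the
#' age-at-death effect: unequal rate reduction across ages.
#'
#' @param baseline,comparison [yll_instance()] objects or rate schedules.
#' @param approach Which population weights define the overall death rate
#'   that the adjustment preserves (`"partial"` = baseline weights).
#' @return A ggplot object.
#' @export
plot_death_rates <- function(baseline, comparison, approach = c("partial", "total")) {
  r0 <- if (inherits(baseline, "yll_rates")) baseline else rate_schedule(as_instance(baseline))
  r1 <- if (inherits(comparison, "yll_rates")) comparison else rate_schedule(as_instance(comparison))
  adj <- adjusted_death_rates(r0, r1, approach)
  d <- tidyr::pivot_longer(
    adj,
    cols = c("dr0", "dr1", "dr0_adjusted"),
    names_to = "schedule", values_to = "dr"
  )
  d$schedule <- factor(
    d$schedule,
    levels = c("dr0", "dr0_adjusted", "dr1"),
    labels = c("Baseline", "Adjusted baseline", "Comparison")
  )
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$age_start, y = .data$dr,
      colour = .data$schedule, linetype = .data$schedule
    )
  ) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::labs(
      x = "Age (years)", y = "Death rate (per 1000)",
      colour = NULL, linetype = NULL,
      title = "Observed and uniformly-adjusted age-specific death rates"
    ) +
    ggplot2::theme_minimal()
}
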