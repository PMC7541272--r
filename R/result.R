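# DecompositionResult assembly and broom-style methods

component_names <- c("age_structure", "death_rate", "age_at_death")

#' Assemble a decomposition result from approach-level components
#'
#' Builds the full report — overall change, residuals, residue-free
#' averages and percentage contributions — from the two YLL rates and the
#' two approaches' component triples.  This is the layer that turns
#' published (or freshly computed) component values into the standard
#' four-row report; [decompose_yll()] calls it after computing the triples
#' from raw data, and it can equally be applied to component values taken
#' from a published table to recover the derived rows.
#'
#' @param yll0,yll1 YLL rates (years per 1000 population) of the baseline
#'   and comparison instance.
#' @param partial,total Named numeric vectors with elements
#'   `age_structure`, `death_rate`, `age_at_death`: the gradients under
#'   the baseline-weighted and comparison-weighted approach.
#' @param labels Character vector of length 2 naming the two instances.
#' @return An object of class `yll_decomposition`: a list with elements
#'   `labels`, `yll0`, `yll1`, `delta_yll`, `partial`, `total` (each a list
#'   of the three gradients plus the derived `death` gradient and
#'   `residual`), `residue_free`, `percent` (unrounded; `NA` with a
#'   `zero_delta` flag when `delta_yll == 0`), `percent_rounded`
#'   (2 decimals, halves away from zero) and `warnings`.
#' @export
#' @examples
#' assemble_decomposition(
#'   yll0 = 691.90, yll1 = 324.21,
#'   partial = c(age_structure = -85.13, death_rate = -305.65, age_at_death = -27.83),
#'   total = c(age_structure = -34.21, death_rate = -258.45, age_at_death = -24.11)
#' )
assemble_decomposition <- function(yll0, yll1, partial, total,
                                   labels = c("baseline", "comparison")) {
  stopifnot(
    is.numeric(yll0), length(yll0) == 1,
    is.numeric(yll1), length(yll1) == 1
  )
  partial <- check_components(partial, "partial")
  total <- check_components(total, "total")
  delta <- yll1 - yll0

  approach_block <- function(comp) {
    list(
      age_structure = unname(comp["age_structure"]),
      death = unname(comp["death_rate"] + comp["age_at_death"]),
      age_at_death = unname(comp["age_at_death"]),
      death_rate = unname(comp["death_rate"]),
      residual = unname(delta - sum(comp))
    )
  }

  rf <- residue_free(partial, total)
  zero_delta <- delta == 0
  pct <- if (zero_delta) {
    stats::setNames(rep(NA_real_, 3), component_names)
  } else {
    percent_contributions(rf, delta)
  }

  structure(
    list(
      labels = labels,
      yll0 = yll0, yll1 = yll1, delta_yll = delta,
      partial = approach_block(partial),
      total = approach_block(total),
      residue_free = rf,
      percent = pct,
      percent_rounded = if (zero_delta) pct else round_half_away(pct, 2),
      zero_delta = zero_delta,
      warnings = character()
    ),
    class = "yll_decomposition"
  )
}

check_components <- function(x, what) {
  if (!is.numeric(x) || !all(component_names %in% names(x))) {
    abort(sprintf(
      "`%s` must be a named numeric vector with elements %s.",
      what, paste0("`", component_names, "`", collapse = ", ")
    ))
  }
  x[component_names]
}

#' Decompose the change in YLL between two instances
#'
#' The package's main entry point.  Harmonizes the two instances and the
#' life table onto a common age schedule, computes the YLL rates, and
#' decomposes their difference into age-structure, death-rate and
#' age-at-death gradients under both the baseline-weighted (partial,
#' Laspeyres-like) and comparison-weighted (total, Paasche-like) approach,
#' together with the residue-free Fisher-style average and percentage
#' contributions.
#'
#' @param baseline,comparison [yll_instance()] objects (or conforming data
#'   frames), instance "0" and instance "1" of the comparison.
#' @param lifetable A [yll_lifetable()]; the same table values both
#'   instances.
#' @param harmonize Aggregate nested age schedules onto common bins first
#'   (default `TRUE`).  With `FALSE`, differing schedules are an error.
#' @return A `yll_decomposition` object (see [assemble_decomposition()]),
#'   additionally carrying `frame` (the aligned per-bin table with columns
#'   `age_start`, `age_end`, `le`, `pw0`, `dr0`, `pw1`, `dr1`) and
#'   `total_population` for both instances.  Methods: [print()],
#'   [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' lt <- yll_lifetable(data.frame(age_start = c(0, 40), le_years = c(70, 35)))
#' i0 <- yll_instance(data.frame(
#'   age_start = c(0, 40), age_end = c(40, NA),
#'   population = c(600, 400), deaths = c(3, 8)
#' ), label = "2000")
#' i1 <- yll_instance(data.frame(
#'   age_start = c(0, 40), age_end = c(40, NA),
#'   population = c(500, 500), deaths = c(1, 9)
#' ), label = "2016")
#' decompose_yll(i0, i1, lt)
decompose_yll <- function(baseline, comparison, lifetable, harmonize = TRUE) {
  baseline <- as_instance(baseline, label = "baseline")
  comparison <- as_instance(comparison, label = "comparison")
  lifetable <- as_lifetable(lifetable)
  if (harmonize) {
    h <- harmonize(baseline, comparison, lifetable)
    baseline <- h$baseline
    comparison <- h$comparison
    lifetable <- h$lifetable
  }
  r0 <- rate_schedule(baseline)
  r1 <- rate_schedule(comparison)

  degenerate <- character()
  triple <- function(approach) {
    split <- withCallingHandlers(
      death_split(r0, r1, lifetable, approach),
      ylldecomp_degenerate_baseline_warning = function(w) {
        degenerate <<- unique(c(degenerate, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    c(
      age_structure = age_structure_gradient(r0, r1, lifetable, approach),
      death_rate = split$death_rate,
      age_at_death = split$age_at_death
    )
  }

  labels <- c(
    attr(baseline, "label", exact = TRUE) %||% "baseline",
    attr(comparison, "label", exact = TRUE) %||% "comparison"
  )
  out <- assemble_decomposition(
    yll0 = yll_rate(r0, lifetable),
    yll1 = yll_rate(r1, lifetable),
    partial = triple("partial"),
    total = triple("total"),
    labels = labels
  )
  for (w in degenerate) warn(w, class = "ylldecomp_degenerate_baseline_warning")
  zero_msg <- if (out$zero_delta) {
    msg <- "Overall change in YLL is zero; percentage contributions are not defined."
    warn(msg, class = "ylldecomp_zero_delta_warning")
    msg
  }
  out$warnings <- c(degenerate, zero_msg)
  out$frame <- comparison_frame(r0, r1, lifetable)
  out$total_population <- c(
    attr(r0, "total_population", exact = TRUE),
    attr(r1, "total_population", exact = TRUE)
  )
  out
}

#' @export
print.yll_decomposition <- function(x, digits = 2, ...) {
  fmt <- function(v) {
    v[abs(v) < 10^(-digits) / 2] <- 0 # avoid printing "-0.00"
    formatC(v, format = "f", digits = digits)
  }
  cat(sprintf(
    "Decomposition of the change in YLL: %s -> %s\n", x$labels[1], x$labels[2]
  ))
  cat(sprintf("  YLL %-12s %s years per 1000\n", x$labels[1], fmt(x$yll0)))
  cat(sprintf("  YLL %-12s %s years per 1000\n", x$labels[2], fmt(x$yll1)))
  cat(sprintf("  delta YLL        %s years per 1000\n\n", fmt(x$delta_yll)))
  rows <- rbind(
    `Total contribution` = c(
      x$total$residual, x$total$age_structure, x$total$death_rate, x$total$age_at_death
    ),
    `Partial contribution` = c(
      x$partial$residual, x$partial$age_structure, x$partial$death_rate, x$partial$age_at_death
    ),
    `Residue-free estimate` = c(
      0, x$residue_free["age_structure"], x$residue_free["death_rate"],
      x$residue_free["age_at_death"]
    )
  )
  colnames(rows) <- c("Residual", "Age structure", "Death rate", "Age at death")
  print(round(rows, digits))
  if (!x$zero_delta) {
    cat(sprintf(
      "\nContribution to delta YLL: age structure %s%%, death rate %s%%, age at death %s%%\n",
      fmt(x$percent["age_structure"]), fmt(x$percent["death_rate"]),
      fmt(x$percent["age_at_death"])
    ))
  } else {
    cat("\nNo overall change in YLL; percentage contributions undefined.\n")
  }
  if (length(x$warnings) > 0) {
    cat("Warnings:\n")
    for (w in x$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}

#' Tidy a YLL decomposition into one row per component and approach
#'
#' @param x A `yll_decomposition` object.
#' @param ... Unused.
#' @return A tibble with columns `component` (`age_structure`,
#'   `death_rate`, `age_at_death`, `residual`), `approach` (`partial`,
#'   `total`, `averaged`), `estimate` (years per 1000) and `percent`
#'   (share of the overall change; only for averaged components).
#' @export
tidy.yll_decomposition <- function(x, ...) {
  approach_rows <- function(block, name) {
    tibble(
      component = c(component_names, "residual"),
      approach = name,
      estimate = c(
        block$age_structure, block$death_rate, block$age_at_death, block$residual
      ),
      percent = NA_real_
    )
  }
  averaged <- tibble(
    component = c(component_names, "residual"),
    approach = "averaged",
    estimate = c(unname(x$residue_free[component_names]), 0),
    percent = c(unname(x$percent[component_names]), NA_real_)
  )
  dplyr::bind_rows(
    approach_rows(x$partial, "partial"),
    approach_rows(x$total, "total"),
    averaged
  )
}

#' One-row summary of a YLL decomposition
#'
#' @param x A `yll_decomposition` object.
#' @param ... Unused.
#' @return A one-row tibble with the instance labels, both YLL rates, the
#'   overall change, the partial-approach residual (the total-approach
#'   residual is its negative), the number of age bins and the number of
#'   warnings raised.
#' @export
glance.yll_decomposition <- function(x, ...) {
  tibble(
    baseline = x$labels[1],
    comparison = x$labels[2],
    yll0 = x$yll0,
    yll1 = x$yll1,
    delta_yll = x$delta_yll,
    residual_partial = x$partial$residual,
    n_bins = if (is.null(x$frame)) NA_integer_ else nrow(x$frame),
    n_warnings = length(x$warnings)
  )
}
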