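# Three-way decomposition of the change in the YLL rate between a baseline
# instance "0" and a comparison instance "1".
#
# Writing the rate as YLL_t = sum_i PW_it * LE_i * DR_it, the change
# delta = YLL_1 - YLL_0 is split into an age-structure gradient (the part
# due to shifting population weights PW at fixed death rates) and a death
# gradient (the part due to changing age-specific death rates DR at fixed
# weights).  The death gradient is further split into a death-rate gradient
# (what a uniform proportional change of all age-specific rates would have
# contributed) and an age-at-death gradient (the remainder: redistribution
# of deaths across ages at a fixed overall death rate).
#
# Each split can weight by the baseline ("partial", Laspeyres-like) or the
# comparison ("total", Paasche-like) instance; the two leave equal and
# opposite residuals, and their mean is exactly additive (Fisher-like).

# internal: align two rate schedules and a life table into one frame
comparison_frame <- function(r0, r1, lifetable) {
  check_same_schedule(r0, r1)
  lifetable <- as_lifetable(lifetable)
  tibble(
    age_start = r0$age_start,
    age_end = r0$age_end,
    le = le_lookup(lifetable, r0$age_start),
    pw0 = r0$pw, dr0 = r0$dr,
    pw1 = r1$pw, dr1 = r1$dr
  )
}

pick_approach <- function(approach) {
  match.arg(approach, c("partial", "total"))
}

#' Overall change in the YLL rate between two instances
#'
#' `sum(pw1 * le * dr1) - sum(pw0 * le * dr0)`, i.e. the comparison's YLL
#' rate minus the baseline's, in years per 1000 population.  Negative
#' values mean the burden fell.
#'
#' @param r0,r1 Rate schedules (see [rate_schedule()]) of the baseline and
#'   comparison instance, on a shared age schedule.
#' @param lifetable A [yll_lifetable()] covering that schedule.
#' @return A single number, years per 1000 population.
#' @export
delta_yll <- function(r0, r1, lifetable) {
  f <- comparison_frame(r0, r1, lifetable)
  sum(f$pw1 * f$le * f$dr1) - sum(f$pw0 * f$le * f$dr0)
}

#' Age-structure gradient of the change in YLL
#'
#' The part of the change attributable to the shift in population age
#' shares, with age-specific death rates held fixed:
#' `sum((pw1 - pw0) * le * dr)` where `dr` is the baseline schedule under
#' the partial (Laspeyres-like) approach and the comparison schedule under
#' the total (Paasche-like) approach.
#'
#' @inheritParams delta_yll
#' @param approach `"partial"` (baseline weights) or `"total"`
#'   (comparison weights).
#' @return Years per 1000 population.
#' @export
age_structure_gradient <- function(r0, r1, lifetable, approach = c("partial", "total")) {
  approach <- pick_approach(approach)
  f <- comparison_frame(r0, r1, lifetable)
  dr <- if (approach == "partial") f$dr0 else f$dr1
  sum((f$pw1 - f$pw0) * f$le * dr)
}

#' Death gradient of the change in YLL
#'
#' The part of the change attributable to changed age-specific death
#' rates, with population age shares held fixed:
#' `sum(pw * le * (dr1 - dr0))` with `pw` from the baseline (partial) or
#' the comparison (total) instance.  Decomposes further into
#' [age_at_death_gradient()] plus [death_rate_gradient()].
#'
#' @inheritParams age_structure_gradient
#' @return Years per 1000 population.
#' @export
death_gradient <- function(r0, r1, lifetable, approach = c("partial", "total")) {
  approach <- pick_approach(approach)
  f <- comparison_frame(r0, r1, lifetable)
  pw <- if (approach == "partial") f$pw0 else f$pw1
  sum(pw * f$le * (f$dr1 - f$dr0))
}

#' Ratio of overall death rates under fixed weights
#'
#' `sum(w * dr1) / sum(w * dr0)` with weights `w` taken from the baseline
#' (partial) or comparison (total) population shares.  This is the uniform
#' scaling factor that, applied to every baseline age-specific rate, would
#' reproduce the comparison's overall (weight-averaged) death rate.
#'
#' @inheritParams age_structure_gradient
#' @return A dimensionless positive number; 1 when the rates are equal.
#'   Errors with class `ylldecomp_degenerate_baseline` when the baseline
#'   weighted death rate is zero.
#' @export
overall_death_rate_ratio <- function(r0, r1, approach = c("partial", "total")) {
  approach <- pick_approach(approach)
  check_same_schedule(r0, r1)
  w <- if (approach == "partial") r0$pw else r1$pw
  den <- sum(w * r0$dr)
  if (den == 0) {
    abort(
      "Baseline weighted overall death rate is zero; the scaling ratio is undefined.",
      class = "ylldecomp_degenerate_baseline"
    )
  }
  sum(w * r1$dr) / den
}

# internal: shared machinery for the two sub-gradients of the death
# gradient.  Returns both at once so they always use the same scaling
# ratio, which makes their sum equal the death gradient exactly.
death_split <- function(r0, r1, lifetable, approach) {
  f <- comparison_frame(r0, r1, lifetable)
  w <- if (approach == "partial") f$pw0 else f$pw1
  den <- sum(w * f$dr0)
  num <- sum(w * f$dr1)
  death <- sum(w * f$le * (f$dr1 - f$dr0))
  if (den == 0) {
    if (num > 0) {
      warn(
        paste(
          "Baseline weighted overall death rate is zero: no baseline age-at-death",
          "pattern exists, so the age-at-death gradient is set to 0 and the whole",
          "death gradient is attributed to the death-rate gradient."
        ),
        class = "ylldecomp_degenerate_baseline_warning"
      )
    }
    return(list(age_at_death = 0, death_rate = death, ratio = NA_real_))
  }
  ratio <- num / den
  base <- sum(w * f$le * f$dr0)
  list(
    age_at_death = sum(w * f$le * f$dr1) - base * ratio,
    death_rate = base * ratio - base,
    ratio = ratio
  )
}

#' Age-at-death gradient
#'
#' The part of the death gradient attributable to redistribution of deaths
#' across age groups at a fixed overall death rate.  With weights `w`
#' (baseline shares for partial, comparison shares for total) and the
#' scaling ratio `ratio = sum(w*dr1)/sum(w*dr0)`, it is
#' `sum(w * le * dr1) - sum(w * le * dr0) * ratio`: the comparison burden minus
#' the burden of a counterfactual schedule with the baseline's age pattern
#' of death scaled to the comparison's overall rate.  Zero whenever
#' `dr1 = c * dr0` for a constant `c > 0` (a purely proportional change
#' carries no age-at-death information).  Negative values mean deaths
#' moved to older ages (less remaining life lost per death).
#'
#' When the baseline weighted death rate is zero there is no baseline age
#' pattern to compare: the gradient is defined as 0, the whole death
#' gradient is carried by [death_rate_gradient()], and a warning of class
#' `ylldecomp_degenerate_baseline_warning` is emitted.
#'
#' @inheritParams age_structure_gradient
#' @return Years per 1000 population.
#' @export
age_at_death_gradient <- function(r0, r1, lifetable, approach = c("partial", "total")) {
  approach <- pick_approach(approach)
  death_split(r0, r1, lifetable, approach)$age_at_death
}

#' Death-rate gradient
#'
#' The part of the death gradient attributable to the change in the
#' overall death rate, i.e. what a uniform proportional change of every
#' age-specific rate would have contributed:
#' `sum(w * le * dr0) * (r - 1)` with the same scaling ratio `r` as
#' [age_at_death_gradient()], so the two always sum to [death_gradient()]
#' exactly.  Negative values mean the overall death rate fell.
#'
#' @inheritParams age_structure_gradient
#' @return Years per 1000 population.
#' @export
death_rate_gradient <- function(r0, r1, lifetable, approach = c("partial", "total")) {
  approach <- pick_approach(approach)
  death_split(r0, r1, lifetable, approach)$death_rate
}

#' Residual of a one-approach decomposition
#'
#' `delta_yll - (age_structure_gradient + death_gradient)` for the chosen
#' approach.  The partial and total residuals are equal in magnitude and
#' opposite in sign (closed form `sum(le * (pw1-pw0) * (dr1-dr0))` for the
#' partial approach), which is why averaging the two approaches gives an
#' exactly additive, residue-free decomposition.
#'
#' @inheritParams age_structure_gradient
#' @return Years per 1000 population.
#' @export
decomposition_residual <- function(r0, r1, lifetable, approach = c("partial", "total")) {
  approach <- pick_approach(approach)
  delta_yll(r0, r1, lifetable) -
    age_structure_gradient(r0, r1, lifetable, approach) -
    death_gradient(r0, r1, lifetable, approach)
}

#' Counterfactual uniformly-scaled baseline death rates
#'
#' The hypothetical age-specific death-rate schedule of a society that
#' achieved the comparison's overall death rate by reducing (or raising)
#' every baseline age-specific rate by the same factor:
#' `dr0 * overall_death_rate_ratio(...)`.  Its weighted overall death rate
#' equals the comparison's exactly; the gap between this schedule and the
#' observed comparison rates is what the age-at-death gradient measures.
#'
#' @inheritParams age_structure_gradient
#' @return A tibble with columns `age_start`, `age_end`, `dr0`, `dr1` and
#'   `dr0_adjusted`.
#' @seealso [plot_death_rates()] for the standard stepwise-change figure.
#' @export
adjusted_death_rates <- function(r0, r1, approach = c("partial", "total")) {
  approach <- pick_approach(approach)
  ratio <- overall_death_rate_ratio(r0, r1, approach)
  tibble(
    age_start = r0$age_start, age_end = r0$age_end,
    dr0 = r0$dr, dr1 = r1$dr, dr0_adjusted = r0$dr * ratio
  )
}

#' Fisher-style residue-free average of the two approaches
#'
#' Componentwise unweighted mean of the partial- and total-approach
#' gradients.  Because the two residuals cancel, the averaged
#' age-structure, death-rate and age-at-death components sum exactly to
#' the overall change in YLL.
#'
#' @param partial,total Named numeric vectors with elements
#'   `age_structure`, `death_rate`, `age_at_death` (extra elements are
#'   averaged too).
#' @return A named numeric vector, the componentwise mean.
#' @export
residue_free <- function(partial, total) {
  comp <- intersect(names(partial), names(total))
  if (length(comp) == 0) {
    # unnamed inputs: plain elementwise mean
    return((partial + total) / 2)
  }
  (partial[comp] + total[comp]) / 2
}

#' Percentage contribution of each component to the overall change
#'
#' `100 * component / delta` for each residue-free component.  Shares sum
#' to 100%; a component opposing the overall change gets a negative share.
#'
#' @param components Named numeric vector of residue-free gradients.
#' @param delta Overall change in the YLL rate (non-zero).
#' @return Named numeric vector of percentages.  Errors with class
#'   `ylldecomp_zero_delta` when `delta == 0` (shares are undefined; report
#'   the gradients themselves instead).
#' @export
percent_contributions <- function(components, delta) {
  if (delta == 0) {
    abort(
      "Overall change in YLL is zero; percentage contributions are undefined.",
      class = "ylldecomp_zero_delta"
    )
  }
  100 * components / delta
}
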