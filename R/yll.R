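#' Total years of life lost to premature death
#'
#' Sums, over age bins, deaths times the conditional life expectancy at the
#' age of death: `sum(deaths_i * le_i)`.  This is the absolute burden in
#' years for the whole population.
#'
#' @param instance An [yll_instance()].
#' @param lifetable A [yll_lifetable()] covering every bin start of the
#'   instance (matched exactly on `age_start`).
#' @return A single non-negative number (years); zero exactly when there
#'   are no deaths.
#' @seealso [yll_rate()] for the population-size-controlled version.
#' @export
#' @examples
#' inst <- yll_instance(data.frame(
#'   age_start = c(0, 5, 15), age_end = c(5, 15, NA),
#'   population = c(200, 300, 500), deaths = c(2, 3, 10)
#' ))
#' lt <- yll_lifetable(data.frame(age_start = c(0, 5, 15), le_years = c(70, 50, 20)))
#' yll_absolute(inst, lt) # 2*70 + 3*50 + 10*20 = 490
yll_absolute <- function(instance, lifetable) {
  instance <- as_instance(instance)
  lifetable <- as_lifetable(lifetable)
  le <- le_lookup(lifetable, instance$age_start)
  sum(instance$deaths * le)
}

#' Years of life lost per 1000 population
#'
#' The burden rate `sum(pw_i * le_i * dr_i)` where `pw_i` is the population
#' share and `dr_i` the death rate per 1000 of age bin `i`.  Algebraically
#' identical to `yll_absolute(...) / total_population * 1000`; the per-1000
#' scale matches how the infant mortality rate and similar indicators are
#' reported, and controls for population size so instances of different
#' sizes can be compared.
#'
#' @inheritParams yll_absolute
#' @return A single number: years of life lost per 1000 population.
#' @export
yll_rate <- function(instance, lifetable) {
  rs <- if (inherits(instance, "yll_rates")) instance else rate_schedule(as_instance(instance))
  lifetable <- as_lifetable(lifetable)
  le <- le_lookup(lifetable, rs$age_start)
  sum(rs$pw * le * rs$dr)
}

#' Aggregate two instances and a life table onto common age bins
#'
#' When the two instances are recorded on different age schedules the
#' comparison is only meaningful if one schedule nests in the other (every
#' boundary of the coarser appears in the finer).  In that case the finer
#' table is aggregated onto the coarser bins — counts sum; life expectancy
#' for a merged bin is the death-weighted mean of its member bins' values,
#' with weights taken from the instance recorded on the finer schedule
#' (the baseline when possible, so its total YLL is preserved exactly),
#' falling back to population weights and then bin widths when the merged
#' bin has no deaths.  Disaggregation is never attempted.
#'
#' @param baseline,comparison [yll_instance()] objects.
#' @param lifetable A [yll_lifetable()] covering the finer schedule.
#' @return A list with elements `baseline`, `comparison`, `lifetable`, all
#'   on the shared (coarser) schedule.  Inputs already on a common schedule
#'   are returned unchanged.  Total population, total deaths, and the
#'   aggregated instance's absolute YLL are conserved.
#' @export
harmonize <- function(baseline, comparison, lifetable) {
  baseline <- as_instance(baseline, label = "baseline")
  comparison <- as_instance(comparison, label = "comparison")
  lifetable <- as_lifetable(lifetable)

  if (same_schedule(baseline, comparison)) {
    le_lookup(lifetable, baseline$age_start) # assert coverage
    return(list(baseline = baseline, comparison = comparison, lifetable = lifetable))
  }

  nests <- function(coarse, fine) {
    all(coarse$age_start %in% fine$age_start) &&
      coarse$age_start[1] == fine$age_start[1] &&
      identical(is.na(coarse$age_end[nrow(coarse)]), is.na(fine$age_end[nrow(fine)])) &&
      (is.na(coarse$age_end[nrow(coarse)]) ||
        coarse$age_end[nrow(coarse)] == fine$age_end[nrow(fine)])
  }

  if (nests(baseline, comparison)) {
    coarse <- baseline
    fine_is_baseline <- FALSE
  } else if (nests(comparison, baseline)) {
    coarse <- comparison
    fine_is_baseline <- TRUE
  } else {
    abort(
      c(
        "Age schedules cannot be harmonized: neither nests in the other.",
        i = "Every bin boundary of the coarser schedule must appear in the finer one."
      ),
      class = "ylldecomp_harmonize_error"
    )
  }

  fine <- if (fine_is_baseline) baseline else comparison
  grp <- findInterval(fine$age_start, coarse$age_start)
  le_fine <- le_lookup(lifetable, fine$age_start)

  agg <- function(x) as.numeric(tapply(x, grp, sum))
  merged <- tibble(
    age_start = coarse$age_start,
    age_end = coarse$age_end,
    population = agg(fine$population),
    deaths = agg(fine$deaths)
  )
  widths <- ifelse(is.na(fine$age_end), 1, fine$age_end - fine$age_start)
  le_merged <- vapply(seq_len(nrow(coarse)), function(g) {
    sel <- grp == g
    w <- fine$deaths[sel]
    if (sum(w) == 0) w <- fine$population[sel]
    if (sum(w) == 0) w <- widths[sel]
    weighted.mean(le_fine[sel], w)
  }, numeric(1))

  merged_instance <- yll_instance(merged, label = attr(fine, "label", exact = TRUE))
  merged_lifetable <- new_lifetable(tibble(
    age_start = coarse$age_start, age_end = coarse$age_end, le_years = le_merged
  ))
  if (fine_is_baseline) {
    list(baseline = merged_instance, comparison = comparison, lifetable = merged_lifetable)
  } else {
    list(baseline = baseline, comparison = merged_instance, lifetable = merged_lifetable)
  }
}
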