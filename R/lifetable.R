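#' Construct a reference life table
#'
#' Conditional life expectancy `le_years` per age bin: the expected
#' remaining years of life for a person alive at the bin's start age.  A
#' single life table is held fixed across every instance being compared, so
#' a death at a given age is valued identically in both — the ethical
#' convention of valuing life on the same scale across space and time.
#' Life expectancy is looked up by exact match on `age_start`; no
#' within-bin interpolation is performed.
#'
#' @param data A data frame with columns `age_start` and `le_years`
#'   (an `age_end` column, if present, is retained but unused).
#' @return A tibble of class `yll_lifetable`.  Validation enforces
#'   `le_years > 0` and the standard life-table consistency property that
#'   `age_start + le_years` is non-decreasing in age (expected age at death
#'   cannot fall as one survives to older ages).
#' @seealso [yll_absolute()], [yll_rate()]
#' @export
#' @examples
#' yll_lifetable(data.frame(age_start = c(0, 5, 15), le_years = c(70, 67, 58)))
yll_lifetable <- function(data) {
  data <- as_tibble(data)
  issues <- validate_lifetable(data)
  if (nrow(issues) > 0) abort_validation(issues, "life table")
  keep <- intersect(c("age_start", "age_end", "le_years"), names(data))
  out <- data[, keep]
  out$age_start <- as.numeric(out$age_start)
  out$le_years <- as.numeric(out$le_years)
  structure(out, class = c("yll_lifetable", class(tibble())))
}

#' Validate a life-table data frame
#'
#' @param data A data frame to check against the life-table contract.
#' @return A tibble of issues (`row`, `column`, `message`); zero rows when
#'   valid.
#' @export
validate_lifetable <- function(data) {
  issues <- check_schedule_columns(data, require_end = FALSE)
  if (!"le_years" %in% names(data)) {
    return(dplyr::bind_rows(issues, new_issue(NA, "le_years", "required column is missing")))
  }
  if (!is.numeric(data$le_years)) {
    return(dplyr::bind_rows(issues, new_issue(NA, "le_years", "must be numeric")))
  }
  if (nrow(issues) > 0) return(issues)
  bad <- which(is.na(data$le_years) | data$le_years <= 0)
  for (i in bad) {
    issues <- dplyr::bind_rows(issues, new_issue(i, "le_years", "life expectancy must be positive"))
  }
  if (nrow(issues) == 0 && nrow(data) > 1) {
    ead <- data$age_start + data$le_years # expected age at death by bin
    bad <- which(diff(ead) < 0) + 1L
    for (i in bad) {
      issues <- dplyr::bind_rows(
        issues,
        new_issue(i, "le_years", "age_start + le_years must be non-decreasing in age")
      )
    }
  }
  issues
}

# internal constructor that skips validation: used for aggregated tables,
# whose death-weighted effective LE need not satisfy the raw monotonicity
# property of a published life table
new_lifetable <- function(data) {
  structure(as_tibble(data), class = c("yll_lifetable", class(tibble())))
}

as_lifetable <- function(x) {
  if (inherits(x, "yll_lifetable")) x else yll_lifetable(x)
}

#' @export
print.yll_lifetable <- function(x, ...) {
  cat(sprintf(
    "<yll_lifetable> %d ages, e(%g) = %.1f years\n",
    nrow(x), x$age_start[1], x$le_years[1]
  ))
  NextMethod()
}
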