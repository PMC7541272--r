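#' Construct an age-binned population/deaths instance
#'
#' An *instance* is one observation of a population at a point in time (or
#' one region): counts of people and deaths per age group.  Age groups are
#' half-open intervals `[age_start, age_end)` in years; the last bin may be
#' open-ended (`age_end = NA`).  Bins must be contiguous, non-overlapping
#' and strictly increasing, with non-negative starts.
#'
#' @param data A data frame with columns `age_start`, `age_end`,
#'   `population`, `deaths`.
#' @param label Free-text label (a year or region name) carried through to
#'   reports.  Defaults to `"instance"`.
#' @return A tibble of class `yll_instance` with the four columns above and
#'   a `label` attribute.  Construction fails with a validation report if
#'   any invariant is violated (negative counts, deaths exceeding
#'   population, non-contiguous bins, zero total population).
#' @seealso [rate_schedule()], [instance_from_rates()], [read_instance()]
#' @export
#' @examples
#' yll_instance(
#'   data.frame(
#'     age_start = c(0, 5, 15), age_end = c(5, 15, NA),
#'     population = c(200, 300, 500), deaths = c(2, 3, 10)
#'   ),
#'   label = "2016"
#' )
yll_instance <- function(data, label = NULL) {
  data <- as_tibble(data)
  issues <- validate_instance(data)
  if (nrow(issues) > 0) abort_validation(issues, "instance")
  out <- data[, c("age_start", "age_end", "population", "deaths")]
  out$age_start <- as.numeric(out$age_start)
  out$age_end <- as.numeric(out$age_end)
  out$population <- as.numeric(out$population)
  out$deaths <- as.numeric(out$deaths)
  structure(out,
    class = c("yll_instance", class(tibble())),
    label = label %||% attr(data, "label", exact = TRUE) %||% "instance"
  )
}

#' Validate an instance table without constructing it
#'
#' Checks every instance invariant and returns the issues found instead of
#' failing, so file readers can report all problems at once.
#'
#' @param data A data frame to check against the instance contract.
#' @return A tibble with columns `row`, `column`, `message`; zero rows when
#'   `data` is a valid instance.
#' @export
validate_instance <- function(data) {
  schedule_issues <- check_schedule_columns(data)
  count_issues <- no_issues()
  structural <- FALSE
  for (col in c("population", "deaths")) {
    if (!col %in% names(data)) {
      count_issues <- dplyr::bind_rows(count_issues, new_issue(NA, col, "required column is missing"))
      structural <- TRUE
    } else if (!is.numeric(data[[col]])) {
      count_issues <- dplyr::bind_rows(count_issues, new_issue(NA, col, "must be numeric"))
      structural <- TRUE
    }
  }
  if (structural) return(dplyr::bind_rows(schedule_issues, count_issues))

  bad <- which(is.na(data$population) | data$population < 0)
  for (i in bad) {
    count_issues <- dplyr::bind_rows(count_issues, new_issue(i, "population", "must be a non-negative number"))
  }
  bad <- which(is.na(data$deaths) | data$deaths < 0)
  for (i in bad) {
    count_issues <- dplyr::bind_rows(count_issues, new_issue(i, "deaths", "must be a non-negative number"))
  }
  # rates are capped at 1000 per 1000: deaths cannot exceed population, and
  # a bin with no population cannot record deaths
  ok <- !is.na(data$population) & !is.na(data$deaths) &
    data$population >= 0 & data$deaths >= 0
  bad <- which(ok & data$deaths > data$population)
  for (i in bad) {
    count_issues <- dplyr::bind_rows(
      count_issues, new_issue(i, "deaths", "deaths exceed population in this age bin")
    )
  }
  if (nrow(data) > 0 && isTRUE(sum(data$population[!is.na(data$population)]) <= 0)) {
    count_issues <- dplyr::bind_rows(
      count_issues, new_issue(NA, "population", "total population must be positive")
    )
  }
  dplyr::bind_rows(schedule_issues, count_issues)
}

# schedule invariants shared by instances and life tables (age_end optional)
check_schedule_columns <- function(data, require_end = TRUE) {
  issues <- no_issues()
  if (!"age_start" %in% names(data)) {
    return(dplyr::bind_rows(issues, new_issue(NA, "age_start", "required column is missing")))
  }
  if (!is.numeric(data$age_start)) {
    return(dplyr::bind_rows(issues, new_issue(NA, "age_start", "must be numeric")))
  }
  if (nrow(data) == 0) {
    return(dplyr::bind_rows(issues, new_issue(NA, "age_start", "at least one age bin is required")))
  }
  if (anyNA(data$age_start)) {
    for (i in which(is.na(data$age_start))) {
      issues <- dplyr::bind_rows(issues, new_issue(i, "age_start", "must not be missing"))
    }
    return(issues)
  }
  if (data$age_start[1] < 0) {
    issues <- dplyr::bind_rows(issues, new_issue(1L, "age_start", "ages must be non-negative"))
  }
  if (is.unsorted(data$age_start, strictly = TRUE)) {
    issues <- dplyr::bind_rows(issues, new_issue(NA, "age_start", "bin starts must be strictly increasing"))
  }
  if (require_end) {
    if (!"age_end" %in% names(data)) {
      return(dplyr::bind_rows(issues, new_issue(NA, "age_end", "required column is missing")))
    }
    n <- nrow(data)
    ends <- data$age_end
    bad_na <- which(is.na(ends)) |> setdiff(n)
    for (i in bad_na) {
      issues <- dplyr::bind_rows(issues, new_issue(i, "age_end", "only the last bin may be open-ended"))
    }
    closed <- which(!is.na(ends))
    for (i in intersect(closed, seq_len(n))) {
      if (ends[i] <= data$age_start[i]) {
        issues <- dplyr::bind_rows(issues, new_issue(i, "age_end", "bin end must exceed bin start"))
      }
    }
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        if (!is.na(ends[i]) && ends[i] != data$age_start[i + 1]) {
          issues <- dplyr::bind_rows(
            issues,
            new_issue(i, "age_end", "bins must be contiguous (end must equal the next bin's start)")
          )
        }
      }
    }
  }
  issues
}

#' Back-fill an instance from population shares and death rates
#'
#' Burden databases often publish age-specific death rates and population
#' weights rather than raw counts.  Given shares `pw` (summing to 1), rates
#' `dr_per_1000` and a total population, counts are reconstructed as
#' `population = pw * total_population` and
#' `deaths = dr_per_1000 * population / 1000`.
#'
#' @param data A data frame with columns `age_start`, `age_end`, `pw`,
#'   `dr_per_1000`.
#' @param total_population Total population the shares refer to (> 0).
#' @inheritParams yll_instance
#' @return A validated [yll_instance()].
#' @export
instance_from_rates <- function(data, total_population, label = NULL) {
  data <- as_tibble(data)
  for (col in c("pw", "dr_per_1000")) {
    if (!col %in% names(data)) {
      abort_validation(new_issue(NA, col, "required column is missing"), "rate table")
    }
  }
  if (!is.numeric(total_population) || length(total_population) != 1 || total_population <= 0) {
    abort("`total_population` must be a single positive number.",
      class = "ylldecomp_validation_error"
    )
  }
  if (any(data$pw < 0) || any(data$dr_per_1000 < 0) || any(data$dr_per_1000 > 1000)) {
    abort_validation(
      new_issue(NA, "pw/dr_per_1000", "shares must be non-negative and rates within [0, 1000]"),
      "rate table"
    )
  }
  if (abs(sum(data$pw) - 1) > 1e-6) {
    abort_validation(new_issue(NA, "pw", "population shares must sum to 1"), "rate table")
  }
  population <- data$pw * total_population
  deaths <- data$dr_per_1000 * population / 1000
  yll_instance(
    tibble(
      age_start = data$age_start, age_end = data$age_end,
      population = population, deaths = deaths
    ),
    label = label
  )
}

#' Convert an instance to its rate schedule
#'
#' Derives the per-bin death rate `dr = deaths / population * 1000` and the
#' population weight `pw = population / total population`.  Bins with zero
#' population get `dr = 0` and `pw = 0` so that all weighted sums stay
#' well-defined; such bins contribute nothing downstream.
#'
#' @param instance An [yll_instance()] (or equivalent data frame).
#' @return A tibble of class `yll_rates` with columns `age_start`,
#'   `age_end`, `pw`, `dr` and attributes `total_population` and `label`.
#'   Weights always satisfy `sum(pw) == 1`.
#' @export
#' @examples
#' inst <- yll_instance(data.frame(
#'   age_start = c(0, 5, 15), age_end = c(5, 15, NA),
#'   population = c(200, 300, 500), deaths = c(2, 3, 10)
#' ))
#' rate_schedule(inst)
rate_schedule <- function(instance) {
  instance <- as_instance(instance)
  total <- sum(instance$population)
  if (total <= 0) {
    abort("Instance has zero total population; rates are undefined.",
      class = "ylldecomp_validation_error"
    )
  }
  dr <- ifelse(instance$population > 0, instance$deaths / instance$population * 1000, 0)
  pw <- instance$population / total
  structure(
    tibble(
      age_start = instance$age_start, age_end = instance$age_end,
      pw = pw, dr = dr
    ),
    class = c("yll_rates", class(tibble())),
    total_population = total,
    label = attr(instance, "label", exact = TRUE) %||% "instance"
  )
}

# accept either a built yll_instance or a plain conforming data frame
as_instance <- function(x, label = NULL) {
  if (inherits(x, "yll_instance")) x else yll_instance(x, label = label)
}

#' @export
print.yll_instance <- function(x, ...) {
  cat(sprintf(
    "<yll_instance: %s> %d age bins, population %s, deaths %s\n",
    attr(x, "label", exact = TRUE) %||% "instance", nrow(x),
    format(sum(x$population), big.mark = ","), format(sum(x$deaths), big.mark = ",")
  ))
  NextMethod()
}
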