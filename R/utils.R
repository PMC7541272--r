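# shared internal helpers: rounding, schedule comparison, LE lookup

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves moved away from zero
#' (so `round_half_away(-0.685, 2)` is `-0.69`), the convention used for the
#' printed percentage rows of decomposition reports.  Base [round()] uses
#' round-half-to-even and would give a different answer on exact halves.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (non-negative integer).
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_away(c(-0.685, 0.125, 2.5), 2)
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  # nudge by a few ulps so values that are conceptually exact halves but are
  # stored just below (e.g. -4.855 -> -4.8549999...) still round away from zero
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# TRUE when two age-binned tables share the same bin boundaries
same_schedule <- function(x, y) {
  if (nrow(x) != nrow(y)) return(FALSE)
  if (!all(x$age_start == y$age_start)) return(FALSE)
  ex <- x$age_end
  ey <- y$age_end
  if (!identical(is.na(ex), is.na(ey))) return(FALSE)
  all(ex[!is.na(ex)] == ey[!is.na(ey)])
}

check_same_schedule <- function(x, y, x_name = "baseline", y_name = "comparison") {
  if (!same_schedule(x, y)) {
    abort(
      c(
        sprintf("`%s` and `%s` are not on the same age schedule.", x_name, y_name),
        i = "Use `harmonize()` to aggregate nested schedules onto common bins."
      ),
      class = "ylldecomp_schedule_error"
    )
  }
  invisible(TRUE)
}

# conditional life expectancy per bin, matched by exact bin start age
le_lookup <- function(lifetable, age_start) {
  idx <- match(age_start, lifetable$age_start)
  if (anyNA(idx)) {
    missing <- age_start[is.na(idx)]
    abort(
      c(
        "Life table has no entry for some age-bin starts.",
        x = sprintf("Missing starts: %s.", paste(missing, collapse = ", ")),
        i = "Life expectancy is looked up by exact match on `age_start`."
      ),
      class = "ylldecomp_schedule_error"
    )
  }
  lifetable$le_years[idx]
}

# format a tibble of (row, column, message) issues into bullet messages
format_issues <- function(issues) {
  vapply(seq_len(nrow(issues)), function(i) {
    loc <- if (is.na(issues$row[i])) {
      issues$column[i]
    } else {
      sprintf("row %d, column `%s`", issues$row[i], issues$column[i])
    }
    sprintf("%s: %s", loc, issues$message[i])
  }, character(1))
}

abort_validation <- function(issues, what) {
  bullets <- format_issues(issues)
  names(bullets) <- rep("x", length(bullets))
  abort(
    c(sprintf("Invalid %s.", what), bullets),
    class = "ylldecomp_validation_error",
    issues = issues
  )
}

new_issue <- function(row, column, message) {
  tibble(row = as.integer(row), column = column, message = message)
}

no_issues <- function() {
  tibble(row = integer(), column = character(), message = character())
}
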