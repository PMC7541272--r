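# CSV readers/writers for instances and life tables, and JSON/CSV report
# output.  Files are UTF-8, comma-separated, "." decimal; age bins are
# half-open [age_start, age_end) with a blank age_end marking the
# open-ended last bin.

count_cols <- c("age_start", "age_end", "population", "deaths")
rate_cols <- c("age_start", "age_end", "pw", "dr_per_1000")

#' Read an instance from CSV
#'
#' Two dialects are supported and auto-detected from the header:
#' * counts: `age_start, age_end, population, deaths`;
#' * rates: `age_start, age_end, pw, dr_per_1000`, with the total
#'   population given in a header comment line
#'   `# total_population: <number>` (counts are then back-filled as in
#'   [instance_from_rates()]).
#'
#' @param path Path to a CSV file.
#' @param dialect `"auto"` (default), `"counts"` or `"rates"`.
#' @param label Label for the instance; defaults to the file name without
#'   extension.
#' @return A validated [yll_instance()].  Malformed files fail with a
#'   validation report listing every offending row and column.
#' @export
read_instance <- function(path, dialect = c("auto", "counts", "rates"), label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "ylldecomp_io_error")
  }
  label <- label %||% tools::file_path_sans_ext(basename(path))
  data <- readr::read_csv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  has_counts <- all(count_cols %in% names(data))
  has_rates <- all(rate_cols %in% names(data))
  if (dialect == "auto") {
    dialect <- if (has_counts) "counts" else if (has_rates) "rates" else {
      abort(
        c(
          "Header matches neither supported dialect.",
          i = sprintf("counts dialect columns: %s", paste(count_cols, collapse = ", ")),
          i = sprintf("rates dialect columns: %s", paste(rate_cols, collapse = ", "))
        ),
        class = "ylldecomp_io_error"
      )
    }
  }
  if (dialect == "counts") {
    if (!has_counts) {
      abort("File does not have the counts-dialect columns.", class = "ylldecomp_io_error")
    }
    yll_instance(data, label = label)
  } else {
    if (!has_rates) {
      abort("File does not have the rates-dialect columns.", class = "ylldecomp_io_error")
    }
    total <- read_total_population_comment(path)
    if (is.na(total)) {
      abort(
        c(
          "Rates-dialect file lacks the total population.",
          i = "Add a header comment line like `# total_population: 250000`."
        ),
        class = "ylldecomp_io_error"
      )
    }
    instance_from_rates(data, total_population = total, label = label)
  }
}

read_total_population_comment <- function(path) {
  header <- readLines(path, n = 10, warn = FALSE)
  m <- grep("^#\\s*total_population\\s*:", header, value = TRUE)
  if (length(m) == 0) return(NA_real_)
  as.numeric(sub("^#\\s*total_population\\s*:\\s*", "", m[1]))
}

#' Write an instance to CSV
#'
#' @param instance An [yll_instance()].
#' @param path Output path.
#' @param dialect `"counts"` (default) writes raw counts; `"rates"` writes
#'   population shares and death rates per 1000 with the total population
#'   in a header comment, the dialect in which burden databases usually
#'   publish.
#' @return `path`, invisibly.  `read_instance(write_instance(x))`
#'   round-trips exactly.
#' @export
write_instance <- function(instance, path, dialect = c("counts", "rates")) {
  dialect <- match.arg(dialect)
  instance <- as_instance(instance)
  if (dialect == "counts") {
    readr::write_csv(as_tibble(instance)[, count_cols], path, na = "")
  } else {
    rs <- rate_schedule(instance)
    total <- attr(rs, "total_population", exact = TRUE)
    lines <- c(
      sprintf("# total_population: %s", format(total, digits = 15, scientific = FALSE)),
      readr::format_csv(
        tibble(
          age_start = rs$age_start, age_end = rs$age_end,
          pw = rs$pw, dr_per_1000 = rs$dr
        ),
        na = ""
      )
    )
    writeLines(sub("\n$", "", lines), path)
  }
  invisible(path)
}

#' Read a reference life table from CSV
#'
#' Expected columns: `age_start, le_years` (an `age_end` column is
#' accepted and kept).
#'
#' @param path Path to a CSV file.
#' @return A validated [yll_lifetable()].
#' @export
read_lifetable <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "ylldecomp_io_error")
  }
  data <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!all(c("age_start", "le_years") %in% names(data))) {
    abort(
      "Life-table file must have columns `age_start` and `le_years`.",
      class = "ylldecomp_io_error"
    )
  }
  yll_lifetable(data)
}

#' Write a life table to CSV
#'
#' @param lifetable A [yll_lifetable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(lifetable, path) {
  lifetable <- as_lifetable(lifetable)
  readr::write_csv(as_tibble(lifetable), path, na = "")
  invisible(path)
}

# report as a plain list mirroring the result object (JSON-ready)
report_list <- function(result) {
  stopifnot(inherits(result, "yll_decomposition"))
  list(
    labels = as.list(result$labels),
    yll0 = result$yll0,
    yll1 = result$yll1,
    delta_yll = result$delta_yll,
    partial = result$partial,
    total = result$total,
    residue_free = as.list(result$residue_free),
    percent = as.list(result$percent),
    percent_rounded = as.list(result$percent_rounded),
    warnings = as.list(result$warnings)
  )
}

#' Write a decomposition report
#'
#' JSON mirrors the `yll_decomposition` object (keys `labels`, `yll0`,
#' `yll1`, `delta_yll`, `partial`, `total`, `residue_free`, `percent`,
#' `percent_rounded`, `warnings`; numbers at full precision).  CSV renders
#' the standard four-row table: the total- and partial-approach
#' contributions, the residue-free estimates, and the percentage
#' contributions, with columns for the residual and the three components.
#' The JSON layout is described by the schema shipped at
#' `system.file("extdata", "decomposition-report.schema.json",
#' package = "ylldecomp")`.
#'
#' @param result A `yll_decomposition` object.
#' @param path Output path.
#' @param format `"json"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      report_list(result), path,
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
  } else {
    readr::write_csv(report_table(result), path, na = "")
  }
  invisible(path)
}

# the four labelled rows of the standard report table
report_table <- function(result) {
  stopifnot(inherits(result, "yll_decomposition"))
  sig <- function(x) signif(x, 12)
  pct <- function(x) if (result$zero_delta) NA_real_ else sig(x)
  tibble(
    row = c(
      "TOTAL Contribution", "PARTIAL Contribution",
      "Residue free estimate", "Contribution in delta YLL (%)"
    ),
    residual = c(sig(result$total$residual), sig(result$partial$residual), 0, NA),
    age_structure = c(
      sig(result$total$age_structure), sig(result$partial$age_structure),
      sig(result$residue_free[["age_structure"]]), pct(result$percent[["age_structure"]])
    ),
    death_rate = c(
      sig(result$total$death_rate), sig(result$partial$death_rate),
      sig(result$residue_free[["death_rate"]]), pct(result$percent[["death_rate"]])
    ),
    age_at_death = c(
      sig(result$total$age_at_death), sig(result$partial$age_at_death),
      sig(result$residue_free[["age_at_death"]]), pct(result$percent[["age_at_death"]])
    )
  )
}

#' Read a JSON decomposition report back into a list
#'
#' @param path Path to a JSON file written by [write_report()].
#' @return A named list with the report keys.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "ylldecomp_io_error")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}
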