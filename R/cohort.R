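#' Descriptive cohort summary
#'
#' Per numeric column (age, weight, disease duration, tremor frequency):
#' count of non-missing values, mean, sample standard deviation (n - 1
#' denominator), minimum and maximum. Missing values are excluded pairwise
#' per column; a column with a single value reports `NA` for the SD, and an
#' all-missing column is skipped with a warning.
#'
#' @param records A cohort `data.frame` as returned by [read_cohort()].
#' @return An object of class `cohort_summary`: a data.frame with one row
#'   per summarized column and columns `variable`, `n`, `mean`, `sd`,
#'   `min`, `max`, at full precision.
#' @seealso [format_cohort_summary()] for table-style rounding.
#' @export
summarize_cohort <- function(records) {
  stopifnot(is.data.frame(records))
  cols <- c("age_years", "weight_kg", "duration_years", "tremor_frequency_hz")
  cols <- intersect(cols, names(records))
  rows <- lapply(cols, function(cn) {
    v <- records[[cn]]
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning(sprintf("column %s has no non-missing values; skipped", cn), call. = FALSE)
      return(NULL)
    }
    data.frame(variable = cn, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               min = min(v), max = max(v))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("cohort_summary", "data.frame"))
}

#' Round a cohort summary to published-table precision
#'
#' Age, weight, and disease duration round to 1 decimal; tremor frequency
#' to 2 decimals.
#'
#' @param x A `cohort_summary`.
#' @return A data.frame with `mean` and `sd` rounded per variable.
#' @export
format_cohort_summary <- function(x) {
  stopifnot(inherits(x, "cohort_summary"))
  digits <- ifelse(x$variable == "tremor_frequency_hz", 2, 1)
  out <- as.data.frame(x)
  out$mean <- round(out$mean, digits)
  out$sd <- round(out$sd, digits)
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (mean, sample SD):\n")
  print(format_cohort_summary(x), row.names = FALSE)
  invisible(x)
}
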