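#' Read and validate a long-format cohort CSV
#'
#' The canonical input is a UTF-8 comma-separated file with the exact
#' header `individual_id,group,day,offspring_count` and one row per
#' (individual, day). Validation enforces, per individual, consecutive days
#' from 1 to the last observed day and a positive final-day count (the
#' operational death definition); every violation is reported with the
#' individual and the offending day.
#'
#' @param path path to the CSV file.
#' @return a cohort data frame (class `cohort`) as produced by
#'   [generate_cohort()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "group", "day", "offspring_count")
  if (!identical(names(df), req))
    stop("cohort file must have the exact header: ",
         paste(req, collapse = ","), " (got: ",
         paste(names(df), collapse = ","), ")")
  if (!is.numeric(df$day) || any(abs(df$day - round(df$day)) > 1e-9) ||
      any(df$day < 1))
    stop("column 'day' must contain positive integers")
  if (!is.numeric(df$offspring_count) || any(df$offspring_count < 0) ||
      any(abs(df$offspring_count - round(df$offspring_count)) > 1e-9))
    stop("column 'offspring_count' must contain non-negative integers")
  df$day <- as.integer(df$day)
  df$offspring_count <- as.integer(df$offspring_count)

  problems <- character(0)
  for (id in unique(df$individual_id)) {
    rows <- df[df$individual_id == id, ]
    days <- sort(rows$day)
    expected <- seq_len(max(days))
    if (!identical(as.integer(days), expected)) {
      missing <- setdiff(expected, days)
      problems <- c(problems, sprintf(
        "individual %s: days are not consecutive from 1 (missing day%s %s)",
        id, if (length(missing) > 1) "s" else "",
        paste(missing, collapse = ", ")))
      next
    }
    if (length(unique(rows$group)) != 1L)
      problems <- c(problems,
                    sprintf("individual %s: inconsistent group labels", id))
    last <- rows$offspring_count[rows$day == max(days)]
    if (last < 1)
      problems <- c(problems, sprintf(
        "individual %s: final-day (day %d) offspring count is 0, violating the death definition",
        id, max(days)))
  }
  if (length(problems) > 0)
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "))
  structure(df, class = c("cohort", "data.frame"))
}

#' Write a cohort to the canonical long-format CSV
#'
#' @param cohort a cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort_df(cohort)
  utils::write.csv(
    cohort[, c("individual_id", "group", "day", "offspring_count")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
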