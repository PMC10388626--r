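#' Write a care-event log as JSON-lines
#'
#' One JSON object per line with ISO-8601 dates, the interchange format for
#' event logs.
#'
#' @param events Event tibble ([generate_event_log()] layout).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  df <- as.data.frame(events)
  df$event_date <- format(df$event_date, "%Y-%m-%d")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}

#' Read a care-event log from JSON-lines
#'
#' @param path File written by [write_events_jsonl()] (or any JSON-lines
#'   file with the same fields).
#' @return Event tibble with `event_date` parsed as `Date`.
#' @export
read_events_jsonl <- function(path) {
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  df$event_date <- as.Date(df$event_date)
  if (!"planned_flag" %in% names(df)) df$planned_flag <- NA
  df$planned_flag <- as.logical(df$planned_flag)
  bad <- setdiff(unique(df$event_type), event_types())
  if (length(bad)) {
    stop(sprintf("unknown event_type(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a patient table (registry or abstract) as UTF-8 CSV
#'
#' Dates are written as ISO-8601 strings, logicals as TRUE/FALSE.
#'
#' @param df Tibble to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patient_csv <- function(df, path) {
  out <- as.data.frame(df)
  for (nm in names(out)) {
    if (inherits(out[[nm]], "Date")) out[[nm]] <- format(out[[nm]], "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' Read a patient-abstract CSV
#'
#' @param path CSV in the [abstract_schema()] layout.
#' @return Tibble with dates and flags restored to their native types.
#' @export
read_abstract_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  for (nm in intersect(names(df), abstract_date_vars())) {
    df[[nm]] <- as.Date(df[[nm]])
  }
  for (nm in intersect(names(df), abstract_flag_vars())) {
    df[[nm]] <- as.logical(df[[nm]])
  }
  tibble::as_tibble(df)
}

#' Read a patient-registry CSV
#'
#' @param path CSV in the [generate_cohort()] layout.
#' @return Registry tibble.
#' @export
read_registry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  df$initial_consult_year <- as.integer(df$initial_consult_year)
  tibble::as_tibble(df)
}
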