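#' Read a screenshot-metadata event stream
#'
#' Accepts JSONL (one JSON object per line with fields `timestamp`,
#' `event_type`, optional `app` and `category`) or CSV with the same
#' columns. Timestamps are ISO-8601 and interpreted as UTC instants.
#'
#' @param path file path; format chosen by extension (`.jsonl`/`.json` vs
#'   `.csv`).
#' @return events tibble for [sessionize()].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort_input("no such event file: ", path)
  if (grepl("\\.jsonl?$", path)) {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("timestamp", "event_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_input("event file ", path, " lacks column(s): ",
                paste(miss, collapse = ", "))
  if (!"app" %in% names(df)) df$app <- NA_character_
  df$timestamp <- parse_instant(df$timestamp)
  tibble::as_tibble(df)
}

#' Write an event stream as JSONL
#'
#' One event per line: ISO-8601 timestamp, event type, app identifier and
#' category where present.
#'
#' @param events events tibble (as produced by [render_event_stream()]).
#' @param path output path.
#' @export
write_events_jsonl <- function(events, path) {
  ev <- events
  ev$timestamp <- format_instant(ev$timestamp)
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(ev), con, verbose = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read an app-to-category map
#'
#' CSV with columns `app`, `category`; category `"social"` marks social
#' apps for the social-screen-time metric.
#'
#' @param path CSV path.
#' @return tibble with `app`, `category`.
#' @export
read_category_map <- function(path) {
  if (!file.exists(path)) abort_input("no such category map: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("app", "category") %in% names(df)))
    abort_input("category map ", path, " needs columns app, category")
  tibble::as_tibble(df)
}

#' Read an item-level survey table
#'
#' @param path CSV path with the layout written by
#'   [generate_survey_series()].
#' @return survey tibble for [score_surveys()].
#' @export
read_surveys <- function(path) {
  if (!file.exists(path)) abort_input("no such survey file: ", path)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an occasion block as CSV
#'
#' @param block tibble/matrix with a `timestamp` column or attribute-free
#'   numeric columns.
#' @param path output path.
#' @export
write_block_csv <- function(block, path) {
  df <- as.data.frame(block)
  if ("timestamp" %in% names(df)) df$timestamp <- format_instant(parse_instant(df$timestamp))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
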