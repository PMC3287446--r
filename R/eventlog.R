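#' Read a usage-event log
#'
#' Parses a portal usage log from CSV or JSON-lines into an ordered event
#' table. Required fields: `timestamp` (ISO-8601, UTC), `ip_key` (opaque
#' anonymized visitor key), `event_type` (one of `search`, `view`,
#' `download`, `taxonomy_download`, `metadata_view`), `dataset_id` (may be
#' empty for `metadata_view`), `records_touched`. An optional `record_ids`
#' field carries semicolon-joined record identifiers; when present its
#' cardinality must equal `records_touched`.
#'
#' Malformed lines (bad timestamp, unknown event type, negative or
#' inconsistent record counts) are never silently dropped: they are removed
#' from the event table and reported line by line in the `errors` tibble.
#'
#' @param path Path to a `.csv` or `.jsonl`/`.ndjson` file.
#' @param format `"csv"`, `"jsonl"`, or `"auto"` (by extension).
#' @return List with `events` (tibble sorted ascending by timestamp, columns
#'   `timestamp`, `ip_key`, `event_type`, `dataset_id`, `records_touched`,
#'   `record_ids` list-column) and `errors` (tibble `line`, `message`).
#' @export
read_events <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    raw <- dplyr::bind_rows(lapply(lines, function(l) {
      rec <- jsonlite::fromJSON(l)
      rec <- lapply(rec, function(v) if (is.null(v)) NA else as.character(v))
      tibble::as_tibble(rec)
    }))
  }
  required <- c("timestamp", "ip_key", "event_type", "dataset_id", "records_touched")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("event log is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"record_ids" %in% names(raw)) raw$record_ids <- NA_character_
  parse_events(raw)
}

#' Validate and order a raw event table
#'
#' Workhorse behind [read_events()]; usable directly on an in-memory data
#' frame with character columns. Returns the same `events` + `errors` pair.
#'
#' @param raw Data frame with the columns documented in [read_events()];
#'   `record_ids` semicolon-joined or a list-column.
#' @return See [read_events()].
#' @export
parse_events <- function(raw) {
  raw <- tibble::as_tibble(raw)
  n <- nrow(raw)
  line <- seq_len(n)

  # readr's own parse warning is redundant here: failures become line-level
  # error records below
  ts <- suppressWarnings(readr::parse_datetime(as.character(raw$timestamp)))
  attr(ts, "tzone") <- "UTC"
  type <- as.character(raw$event_type)
  touched <- suppressWarnings(as.numeric(raw$records_touched))
  ids <- raw$record_ids
  if (!is.list(ids)) {
    ids <- lapply(as.character(ids), function(x) {
      if (is.na(x) || !nzchar(x)) NULL else strsplit(x, ";", fixed = TRUE)[[1]]
    })
  }
  n_ids <- vapply(ids, function(x) if (is.null(x)) NA_integer_ else length(unique(x)),
                  integer(1))

  msg <- rep(NA_character_, n)
  bad <- function(cond, text) {
    cond <- !is.na(cond) & cond
    msg[is.na(msg) & cond] <<- text
  }
  bad(is.na(ts), "unparseable timestamp")
  bad(!type %in% EVENT_TYPES,
      paste0("unknown event_type (expected one of: ", paste(EVENT_TYPES, collapse = ", "), ")"))
  bad(is.na(touched) | touched < 0 | touched != trunc(touched),
      "records_touched must be a non-negative integer")
  bad(type == "metadata_view" & touched > 0, "metadata_view must touch 0 records")
  bad(!is.na(n_ids) & n_ids != touched,
      "record_ids cardinality differs from records_touched")
  missing_ip <- is.na(raw$ip_key) | !nzchar(as.character(raw$ip_key))
  bad(missing_ip, "missing ip_key")

  ok <- is.na(msg)
  events <- tibble::tibble(
    timestamp = ts[ok],
    ip_key = as.character(raw$ip_key)[ok],
    event_type = type[ok],
    dataset_id = as.character(raw$dataset_id)[ok],
    records_touched = as.integer(touched[ok]),
    record_ids = ids[ok])
  ord <- order(events$timestamp)
  events <- events[ord, ]
  errors <- tibble::tibble(line = line[!ok], message = msg[!ok])
  if (nrow(errors)) {
    warn(sprintf("%d of %d event line(s) malformed; see $errors", nrow(errors), n))
  }
  list(events = events, errors = errors)
}

#' Remove bounce events
#'
#' A bounce is a portal visit that touches metadata only and no dataset
#' records: every `metadata_view` event, and any search/view event with zero
#' records touched. Bounces carry no usable signal for record-level
#' indicators and are removed before any counting; the removed share is
#' reported (portal-wide bounce rates around two thirds are typical) but
#' used nowhere else.
#'
#' @param events Event tibble from [read_events()]/[parse_events()].
#' @return List with `events` (kept rows) and `bounce_fraction`
#'   (removed/total; 0 for an empty log).
#' @export
filter_bounces <- function(events) {
  n <- nrow(events)
  is_bounce <- events$event_type == "metadata_view" |
    (events$event_type %in% INTEREST_TYPES & events$records_touched == 0)
  list(events = events[!is_bounce, ],
       bounce_fraction = if (n == 0) 0 else sum(is_bounce) / n)
}

#' Reconstruct sessions with the 30-minute inactivity rule
#'
#' Events from one `ip_key` belong to the same session while consecutive
#' gaps stay under `gap_minutes`; an inactivity of at least `gap_minutes`
#' (the boundary gap itself splits) starts a new session. The first session
#' of an ip key in the log is a unique visit; every later session is a loyal
#' (returning) one.
#'
#' @param events Event tibble (any order; sorted internally per ip key).
#' @param gap_minutes Positive inactivity threshold in minutes (default 30).
#' @return Tibble with one row per session: `session_id`, `ip_key`, `start`,
#'   `end`, `n_events`, `loyal`.
#' @export
sessionize <- function(events, gap_minutes = 30) {
  if (!is.numeric(gap_minutes) || length(gap_minutes) != 1 || gap_minutes <= 0) {
    abort("gap_minutes must be a single positive number")
  }
  if (nrow(events) == 0) {
    return(tibble::tibble(session_id = character(), ip_key = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          n_events = integer(), loyal = logical()))
  }
  gap_s <- gap_minutes * 60
  events |>
    dplyr::arrange(.data$ip_key, .data$timestamp) |>
    dplyr::group_by(.data$ip_key) |>
    dplyr::mutate(
      gap = as.numeric(.data$timestamp) - dplyr::lag(as.numeric(.data$timestamp)),
      new_session = is.na(.data$gap) | .data$gap >= gap_s,
      session_index = cumsum(.data$new_session)) |>
    dplyr::group_by(.data$ip_key, .data$session_index) |>
    dplyr::summarise(start = min(.data$timestamp), end = max(.data$timestamp),
                     n_events = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(loyal = .data$session_index > 1,
                  session_id = paste0(.data$ip_key, "#", .data$session_index)) |>
    dplyr::select("session_id", "ip_key", "start", "end", "n_events", "loyal")
}

#' Raw event counts for one unit and window
#'
#' Aggregates a bounce-filtered event stream into the raw quantities behind
#' the indicators, restricted to the unit's member datasets and to events
#' with `start <= timestamp < end`:
#' searched records `s` and search events `S` (search/view types),
#' downloaded records `d` and download events `D` (download and taxonomy
#' download types), unique downloaded/searched records `U`/`I` (distinct
#' record ids; `NA` when any contributing event lacks ids), and `n`, the
#' number of member datasets with at least one counted event.
#'
#' @param events Bounce-filtered event tibble.
#' @param registry A `dui_registry`.
#' @param unit_id Unit to count for.
#' @param window An [analysis_window()].
#' @param level Optional unit level for disambiguation.
#' @return One-row tibble: `unit_id`, `window`, `s`, `d`, `S`, `D`, `U`,
#'   `I`, `n`.
#' @export
count_events <- function(events, registry, unit_id, window, level = NULL) {
  stopifnot(inherits(window, "analysis_window"))
  members <- member_datasets(registry, unit_id, level)
  ev <- events[in_window(events$timestamp, window) & events$dataset_id %in% members, ]

  interest <- ev[ev$event_type %in% INTEREST_TYPES, ]
  usage <- ev[ev$event_type %in% USAGE_TYPES, ]

  unique_ids <- function(block) {
    if (nrow(block) == 0) return(0L)
    idl <- block$record_ids
    if (any(vapply(idl, is.null, logical(1)))) return(NA_integer_)
    length(unique(unlist(idl, use.names = FALSE)))
  }

  tibble::tibble(
    unit_id = unit_id,
    window = window$label,
    s = sum(interest$records_touched),
    d = sum(usage$records_touched),
    S = nrow(interest),
    D = nrow(usage),
    U = unique_ids(usage),
    I = unique_ids(interest),
    n = length(unique(ev$dataset_id)))
}
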