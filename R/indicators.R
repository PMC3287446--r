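#' Compute the full indicator set for a unit and window
#'
#' Derives the fourteen usage-index indicators from raw counts. The six
#' absolute inputs are the searched records `s`, downloaded records `d`,
#' stored records `r`, search events `S`, download events `D` and dataset
#' number `N` (plus `n`, the member datasets actually used). The derived
#' indicators are:
#'
#' * `search_density`  = s/S - records retrieved per search event
#' * `download_density` = d/D - records downloaded per download event
#' * `usage_impact`    = d/r - downloads per stored record (UIF)
#' * `interest_impact` = s/r - searches per stored record (IIF)
#' * `usage_ratio`     = d/s - share of searched records that were downloaded
#' * `usage_balance`   = D/S - share of search events leading to a download
#' * `usage_score`     = 100 U/r - % of stored records downloaded at least once
#' * `interest_score`  = 100 I/r - % of stored records searched at least once
#'
#' Any ratio with a zero denominator is undefined and returned as `NA`,
#' never as 0 or infinity; scores are `NA` whenever the unique-record counts
#' `U`/`I` are unavailable. All values are kept at full precision — see
#' [display_indicators()] for the conventional rounding.
#'
#' @param counts One- or multi-row data frame with columns `s`, `d`, `S`,
#'   `D` and optionally `U`, `I`, `n`, `unit_id`, `window` (as produced by
#'   [count_events()]).
#' @param r Stored-record count(s) r(u), recycled across rows.
#' @param N Dataset count(s) N(u), recycled across rows.
#' @return Tibble with one row per input row and all indicator columns.
#' @examples
#' compute_indicator_set(
#'   data.frame(s = 2092927, d = 555835, S = 42860, D = 601),
#'   r = 11140298, N = 180)
#' @export
compute_indicator_set <- function(counts, r, N) {
  counts <- tibble::as_tibble(counts)
  need <- c("s", "d", "S", "D")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    abort(paste0("counts is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  nr <- nrow(counts)
  r <- rep_len(as.numeric(r), nr)
  N <- rep_len(as.numeric(N), nr)
  U <- if ("U" %in% names(counts)) as.numeric(counts$U) else rep(NA_real_, nr)
  I <- if ("I" %in% names(counts)) as.numeric(counts$I) else rep(NA_real_, nr)
  n <- if ("n" %in% names(counts)) as.numeric(counts$n) else rep(NA_real_, nr)

  vals <- cbind(counts$s, counts$d, counts$S, counts$D, r, N)
  if (any(vals < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE) || any(I < 0, na.rm = TRUE)) {
    abort("counts and denominators must be non-negative")
  }
  if (any(U > r, na.rm = TRUE) || any(I > r, na.rm = TRUE)) {
    abort("unique record counts U/I cannot exceed the stored record number r")
  }

  s <- as.numeric(counts$s); d <- as.numeric(counts$d)
  S <- as.numeric(counts$S); D <- as.numeric(counts$D)
  tibble::tibble(
    unit_id = if ("unit_id" %in% names(counts)) counts$unit_id else NA_character_,
    window = if ("window" %in% names(counts)) counts$window else NA_character_,
    s = s, d = d, r = r, S = S, D = D, N = N, n = n,
    search_density = ratio_or_na(s, S),
    download_density = ratio_or_na(d, D),
    usage_impact = ratio_or_na(d, r),
    interest_impact = ratio_or_na(s, r),
    usage_ratio = ratio_or_na(d, s),
    usage_balance = ratio_or_na(D, S),
    usage_score = 100 * ratio_or_na(U, r),
    interest_score = 100 * ratio_or_na(I, r))
}

#' Usage and interest scores
#'
#' Share of a unit's stored records touched at least once in the window:
#' the usage score uses unique downloaded records `U`, the interest score
#' unique searched records `I`. Both are the usage analogue of citedness.
#'
#' @param U Unique downloaded (or searched, for the interest score) record
#'   count; must satisfy `0 <= U <= r`.
#' @param r Stored-record count, `r > 0`.
#' @return Percentage in `[0, 100]`.
#' @export
usage_score <- function(U, r) {
  if (any(r <= 0)) abort("usage_score requires r > 0")
  if (any(U < 0) || any(U > r)) {
    abort("U must satisfy 0 <= U <= r (a unit cannot have more unique downloaded records than stored records)")
  }
  100 * U / r
}

#' @rdname usage_score
#' @param I Unique searched record count.
#' @export
interest_score <- function(I, r) usage_score(I, r)

#' Indicator time series over consecutive windows
#'
#' Computes one indicator set per analysis window for a unit, holding the
#' stored-record denominator r(u) to the registry snapshot under each
#' window's record-count convention (with a single inventory snapshot the
#' denominator is identical across windows, which keeps impact factors
#' comparable along the series).
#'
#' @param events Bounce-filtered event tibble.
#' @param registry A `dui_registry`.
#' @param unit_id Unit identifier.
#' @param windows List of non-overlapping [analysis_window()] objects.
#' @param level Optional unit level.
#' @return Tibble with one indicator-set row per window, in the given order.
#' @export
time_series <- function(events, registry, unit_id, windows, level = NULL) {
  if (inherits(windows, "analysis_window")) windows <- list(windows)
  if (!length(windows)) abort("at least one analysis window is required")
  if (windows_overlap(windows)) abort("analysis windows must not overlap")
  N <- dataset_number(registry, unit_id, level)
  rows <- lapply(windows, function(w) {
    counts <- count_events(events, registry, unit_id, w, level)
    r <- record_number(registry, unit_id, level, window = w)
    compute_indicator_set(counts, r = as.numeric(r), N = N)
  })
  dplyr::bind_rows(rows)
}

#' Round an indicator table for display
#'
#' Applies the conventional display rounding (half-up): two decimals for
#' densities, impacts, ratios and scores, three decimals for the usage
#' balance, whose typical magnitude is a few thousandths. Internally all
#' indicators are full precision; rounding is display-only.
#'
#' @param ind Indicator tibble from [compute_indicator_set()].
#' @param balance_percent If `TRUE`, report `usage_balance` as a percentage
#'   (two decimals) instead of a plain ratio (three decimals).
#' @return The tibble with derived columns rounded.
#' @export
display_indicators <- function(ind, balance_percent = FALSE) {
  two <- c("search_density", "download_density", "usage_impact",
           "interest_impact", "usage_ratio", "usage_score", "interest_score")
  for (col in intersect(two, names(ind))) ind[[col]] <- round_half_up(ind[[col]], 2)
  if ("usage_balance" %in% names(ind)) {
    ind$usage_balance <- if (balance_percent) {
      round_half_up(100 * ind$usage_balance, 2)
    } else {
      round_half_up(ind$usage_balance, 3)
    }
  }
  ind
}

#' Write an indicator table to CSV and JSON
#'
#' Tidy output: one row per (unit, window), columns named as in
#' [compute_indicator_set()], period decimal separator, no thousands
#' separators. The JSON mirror holds the same rows as an array of objects.
#'
#' @param ind Indicator tibble.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `ind`, invisibly.
#' @export
write_indicators <- function(ind, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(ind, csv_path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(ind, json_path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(ind)
}
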