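#' Define an analysis window
#'
#' Usage indicators are always computed for a bounded observation window.
#' Windows are half-open intervals `[start, end)` so that adjacent windows
#' partition a period without double counting events on the joint.
#'
#' @param start,end Window bounds as `POSIXct` or ISO-8601 strings,
#'   interpreted as UTC. `start` must precede `end`.
#' @param label Short window label used in output tables (defaults to
#'   `"start/end"`).
#' @param record_count_convention How the stored-record denominator r(u) is
#'   read off the inventory for this window. Inventories are point-in-time
#'   snapshots, so with a single snapshot all conventions yield the same
#'   number; the convention is recorded so that multi-snapshot extensions and
#'   report manifests stay explicit. Default `"end_of_window"`, matching the
#'   usual practice of freezing denominators at the closing date of the
#'   analysis period.
#' @return An `analysis_window` object (a list with `start`, `end`, `label`,
#'   `record_count_convention`).
#' @examples
#' analysis_window("2009-07-01", "2010-01-01", label = "2009b")
#' @export
analysis_window <- function(start, end, label = NULL,
                            record_count_convention = c("end_of_window", "current",
                                                        "window_average")) {
  record_count_convention <- match.arg(record_count_convention)
  start <- parse_utc(start)
  end <- parse_utc(end)
  if (anyNA(c(start, end)) || length(start) != 1 || length(end) != 1) {
    abort("window bounds must be single parseable UTC timestamps")
  }
  if (!(start < end)) abort("window start must be strictly before end")
  label <- label %||% paste(format(start, "%Y-%m-%d"), format(end, "%Y-%m-%d"), sep = "/")
  structure(list(start = start, end = end, label = label,
                 record_count_convention = record_count_convention),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window> %s: [%s, %s) UTC, r(u) convention: %s\n",
              x$label, format(x$start), format(x$end), x$record_count_convention))
  invisible(x)
}

in_window <- function(timestamps, window) {
  timestamps >= window$start & timestamps < window$end
}

windows_overlap <- function(windows) {
  if (length(windows) < 2) return(FALSE)
  starts <- vapply(windows, function(w) as.numeric(w$start), numeric(1))
  ends <- vapply(windows, function(w) as.numeric(w$end), numeric(1))
  ord <- order(starts)
  any(ends[ord][-length(ord)] > starts[ord][-1])
}
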