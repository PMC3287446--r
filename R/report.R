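#' Run configuration for a reproducible indicator computation
#'
#' Bundles input paths, analysis windows and options for [run_compute()].
#' Reproducibility of usage analyses depends on frozen inputs, so every run
#' writes a snapshot manifest of input-file digests; a later run against the
#' same output directory and snapshot label fails loudly if any input file
#' changed.
#'
#' @param inventory Path to the dataset inventory CSV.
#' @param events Path to the event log (CSV or JSONL).
#' @param windows List of [analysis_window()]s, or strings
#'   `"YYYY-MM-DD:YYYY-MM-DD"`.
#' @param species,record_ids Optional paths to the species and record-id
#'   tables.
#' @param level Unit level to report on (default `"publisher"`).
#' @param units Optional character vector restricting to specific unit ids.
#' @param rounding `"full"` (full-precision output) or `"display"`
#'   (conventional display rounding via [display_indicators()]).
#' @param out_dir Output directory.
#' @param label Snapshot label (defaults to `"snapshot"`).
#' @return A `run_config` list.
#' @export
run_config <- function(inventory, events, windows, species = NULL,
                       record_ids = NULL, level = "publisher", units = NULL,
                       rounding = c("full", "display"), out_dir = ".",
                       label = "snapshot") {
  rounding <- match.arg(rounding)
  if (inherits(windows, "analysis_window")) windows <- list(windows)
  windows <- lapply(windows, function(w) {
    if (inherits(w, "analysis_window")) return(w)
    parts <- strsplit(w, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) abort("window strings must be 'start:end'")
    analysis_window(parts[1], parts[2])
  })
  paths <- c(inventory = inventory, events = events,
             species = species, record_ids = record_ids)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    abort(paste0("input file(s) not found: ", paste(missing_files, collapse = ", ")))
  }
  structure(list(inventory = inventory, events = events, species = species,
                 record_ids = record_ids, windows = windows, level = level,
                 units = units, rounding = rounding, out_dir = out_dir,
                 label = label),
            class = "run_config")
}

#' Compute and write an indicator report
#'
#' Reads the inventory and event log, filters bounces, computes the full
#' indicator set for every requested unit and window, and writes
#' `indicators.csv`, `indicators.json` and a snapshot manifest
#' (`manifest_<label>.json` with input digests, a config echo and the
#' package version) to the output directory. Identical inputs produce
#' byte-identical outputs; re-running against an existing manifest with
#' changed inputs is an error.
#'
#' @param config A [run_config()].
#' @return The indicator tibble, invisibly; attribute `bounce_fraction`
#'   carries the share of bounce events removed.
#' @export
run_compute <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  in_paths <- c(inventory = config$inventory, events = config$events,
                species = config$species, record_ids = config$record_ids)
  digests <- vapply(in_paths, function(p) unname(tools::md5sum(p)), character(1))
  manifest_path <- file.path(config$out_dir,
                             paste0("manifest_", config$label, ".json"))
  if (file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    old_digests <- unlist(old$input_digests)
    if (!identical(sort(names(old_digests)), sort(names(digests))) ||
        any(old_digests[names(digests)] != digests)) {
      abort(paste0("snapshot '", config$label, "' already exists in ",
                   config$out_dir, " with different input digests; ",
                   "refusing to overwrite a frozen snapshot"))
    }
  }

  inv <- read_inventory(config$inventory, config$species, config$record_ids)
  registry <- build_registry(inv)
  parsed <- read_events(config$events)
  filtered <- filter_bounces(parsed$events)
  if (nrow(filtered$events) == 0) {
    warn("no record-touching events in the log; report will be all zero")
  }

  unit_ids <- config$units %||%
    registry$units$unit_id[registry$units$level == config$level]
  rows <- lapply(unit_ids, function(u) {
    time_series(filtered$events, registry, u, config$windows,
                level = config$level)
  })
  ind <- dplyr::bind_rows(rows)
  out <- if (config$rounding == "display") display_indicators(ind) else ind

  write_indicators(out,
                   csv_path = file.path(config$out_dir, "indicators.csv"),
                   json_path = file.path(config$out_dir, "indicators.json"))
  manifest <- list(
    snapshot = config$label,
    tool = list(package = "duindex",
                version = as.character(utils::packageVersion("duindex"))),
    input_digests = as.list(digests),
    config = list(level = config$level, units = config$units,
                  rounding = config$rounding,
                  windows = lapply(config$windows, function(w) {
                    list(start = format(w$start, "%Y-%m-%dT%H:%M:%SZ"),
                         end = format(w$end, "%Y-%m-%dT%H:%M:%SZ"),
                         label = w$label,
                         record_count_convention = w$record_count_convention)
                  })))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  attr(ind, "bounce_fraction") <- filtered$bounce_fraction
  invisible(ind)
}

#' Annual usage report for publishers
#'
#' The usage analogue of a journal citation report: one row per publisher
#' with its dataset count `N`, datasets used `n`, stored records `r`,
#' searched and downloaded records, usage and interest impact factors, the
#' species-profile-weighted crown indicator (when the inventory carries a
#' species table), size class, and rank by usage impact. Ties in UIF are
#' broken by stored records (descending) and then by unit id, so the
#' ranking is deterministic.
#'
#' @param events Bounce-filtered event tibble.
#' @param registry A `dui_registry`.
#' @param window An [analysis_window()].
#' @return Tibble ranked by `uif` descending (undefined UIFs last).
#' @export
annual_report <- function(events, registry, window) {
  pubs <- registry$units$unit_id[registry$units$level == "publisher"]
  baseline <- NULL
  profiles <- NULL
  if (!is.null(registry$inventory$species)) {
    profiles <- species_profiles(events, registry, window, level = "publisher")
    world <- species_profiles(events, registry, window, level = "world")
    if (nrow(world)) baseline <- species_baseline(world)
  }
  rows <- lapply(pubs, function(p) {
    counts <- count_events(events, registry, p, window, level = "publisher")
    r <- record_number(registry, p, level = "publisher", window = window)
    N <- dataset_number(registry, p, level = "publisher")
    uci <- NA_real_
    if (!is.null(baseline) && !is.null(profiles)) {
      prof <- profiles[profiles$unit_id == p, ]
      if (nrow(prof) && sum(prof$records) > 0) {
        uci <- usage_crown_indicator(prof, baseline)
      }
    }
    tibble::tibble(
      unit_id = p, N = N, n = counts$n, r = as.numeric(r),
      s = counts$s, d = counts$d,
      uif = ratio_or_na(counts$d, as.numeric(r)),
      iif = ratio_or_na(counts$s, as.numeric(r)),
      uci = uci,
      size_class = size_class_of(N))
  })
  report <- dplyr::bind_rows(rows)
  ord <- order(-replace(report$uif, is.na(report$uif), -Inf),
               -report$r, report$unit_id)
  report <- report[ord, ]
  report$rank <- seq_len(nrow(report))
  report
}

#' Write an annual report as CSV and readable text
#'
#' @param report Tibble from [annual_report()].
#' @param csv_path,txt_path Output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_annual_report <- function(report, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(report, csv_path, progress = FALSE)
  if (!is.null(txt_path)) {
    disp <- report
    for (col in c("uif", "iif", "uci")) disp[[col]] <- round_half_up(disp[[col]], 2)
    lines <- c("Publisher usage report (ranked by usage impact factor)",
               paste(rep("-", 72), collapse = ""),
               utils::capture.output(print(as.data.frame(disp), row.names = FALSE)))
    writeLines(lines, txt_path)
  }
  invisible(report)
}
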