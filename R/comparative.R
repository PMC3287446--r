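#' Relative usage/interest impact index
#'
#' Expresses a unit's usage impact factor (UIF = d/r, downloads per stored
#' record) relative to a baseline aggregate, producing an index in which 1.0
#' is the baseline performance. The baseline UIF is formed by the ratio of
#' sums over its `n` member units — total downloads over total stored
#' records — so large datasets weight the baseline more than small ones.
#' Passing searched records `s` in place of `d` yields the analogous
#' interest-impact (IIF) index.
#'
#' Two modes control an arithmetic subtlety of published tables: in
#' `"full"` (default) mode both impact factors keep full precision before
#' the division; in `"rounded"` mode each absolute impact factor is first
#' rounded half-up to two decimals, reproducing indices computed from a
#' printed table's two-decimal entries (e.g. 6.50/0.32 = 20.31, where full
#' precision gives 19.99).
#'
#' @param d Downloaded (or searched) record count of the unit.
#' @param r Stored record count of the unit (> 0).
#' @param baseline Data frame (or list) with elements/columns `d` and `r`
#'   giving downloads and stored records for each baseline unit; the
#'   baseline may and normally does contain the unit itself.
#' @param mode `"full"` or `"rounded"`.
#' @return The index value; `NA` with a warning when the baseline has zero
#'   stored records or a zero baseline impact.
#' @examples
#' relative_index(717102, 259077, list(d = 1571863, r = 4836771), mode = "rounded")
#' @export
relative_index <- function(d, r, baseline, mode = c("full", "rounded")) {
  mode <- match.arg(mode)
  if (r <= 0) abort("unit stored-record count r must be positive")
  bd <- sum(as.numeric(baseline$d))
  br <- sum(as.numeric(baseline$r))
  if (br <= 0) {
    warn("baseline has zero stored records; relative index undefined")
    return(NA_real_)
  }
  uif_unit <- d / r
  uif_base <- bd / br
  if (mode == "rounded") {
    uif_unit <- round_half_up(uif_unit, 2)
    uif_base <- round_half_up(uif_base, 2)
  }
  if (uif_base == 0) {
    warn("baseline impact factor is zero; relative index undefined")
    return(NA_real_)
  }
  uif_unit / uif_base
}

#' Expected global per-species impact baseline
#'
#' From the species profiles of a set of reference units, computes for each
#' species the expected global UIF: total downloads of that species across
#' all reference units over total stored records, i.e. a ratio of sums, so
#' units holding many records of a species weight its expectation more.
#' Species with zero stored records across the reference set are omitted
#' (with a warning): no expectation is defined for them.
#'
#' @param profiles Long data frame with columns `unit_id`, `species`,
#'   `records`, `downloads` — one row per (reference unit, species).
#' @return Tibble `species`, `expected_uif`, with attribute `n_units` (the
#'   number of reference units aggregated).
#' @export
species_baseline <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  need <- c("unit_id", "species", "records", "downloads")
  missing_cols <- setdiff(need, names(profiles))
  if (length(missing_cols)) {
    abort(paste0("profiles is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(profiles) == 0) abort("at least one species profile row is required")
  agg <- profiles |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(r = sum(.data$records), d = sum(.data$downloads),
                     .groups = "drop")
  zero <- agg$species[agg$r == 0]
  if (length(zero)) {
    warn(paste0("species with zero stored records omitted from baseline: ",
                paste(zero, collapse = ", ")))
    agg <- agg[agg$r > 0, ]
  }
  out <- tibble::tibble(species = agg$species, expected_uif = agg$d / agg$r)
  attr(out, "n_units") <- length(unique(profiles$unit_id))
  out
}

#' Species-profile-weighted Usage Crown Indicator
#'
#' Field-normalized usage impact: observed downloads of a unit over the
#' downloads expected given its species profile. For each of the `p` species
#' in the unit's profile the expected downloads are the stored records
#' `r_s` times the global expected UIF of that species, and
#' `UCI = d(u) / sum(r_s * U_s)`. A value of 1.0 means the unit is used
#' exactly on par with the global (or regional) baseline once its species
#' mix is accounted for; the indicator is the usage analogue of the
#' field-normalized crown indicators of citation analysis.
#'
#' @param profile Data frame `species`, `records` (stored records per
#'   species in the unit). A `downloads` column is used for the default
#'   `d_total`.
#' @param baseline A [species_baseline()] table (or any data frame
#'   `species`, `expected_uif`). Every profile species must be present:
#'   silently skipping unmatched species would change `p` and bias the
#'   indicator, so orphans raise an error listing them.
#' @param d_total Total downloaded records of the unit; defaults to
#'   `sum(profile$downloads)`.
#' @return The UCI value; `NA` with a warning when the expected download sum
#'   is zero.
#' @export
usage_crown_indicator <- function(profile, baseline, d_total = NULL) {
  profile <- tibble::as_tibble(profile)
  if (!all(c("species", "records") %in% names(profile))) {
    abort("profile needs columns species and records")
  }
  profile <- profile[profile$records > 0, ]
  if (is.null(d_total)) {
    if (!"downloads" %in% names(profile)) {
      abort("supply d_total or a downloads column in the profile")
    }
    d_total <- sum(profile$downloads)
  }
  orphans <- setdiff(profile$species, baseline$species)
  if (length(orphans)) {
    abort(paste0("profile species missing from the baseline: ",
                 paste(sort(orphans), collapse = ", ")))
  }
  u_s <- baseline$expected_uif[match(profile$species, baseline$species)]
  expected <- sum(profile$records * u_s)
  if (expected == 0) {
    warn("expected downloads are zero for this profile; UCI undefined")
    return(NA_real_)
  }
  d_total / expected
}

#' Brute-force size adjustment
#'
#' Comparing units of very different sizes on impact factors alone is
#' unfair to large publishers; the brute-force parameter rescales a
#' normalized, relative or weighted impact value by the unit's stored
#' records in millions, `value * r / 1e6`, so that ultra-large publishers
#' group apart from small ones in rankings.
#'
#' @param value Impact-factor-like value(s).
#' @param r Stored record count(s), recycled.
#' @return Adjusted value(s).
#' @export
brute_force_adjust <- function(value, r) {
  if (any(r < 0, na.rm = TRUE)) abort("r must be non-negative")
  value * r / 1e6
}

#' Species profiles estimated from inventory and events
#'
#' Builds long species-profile tables (stored records and downloads per
#' species) for units at a given level. Stored records per species come
#' from the inventory's species table. Event logs record which dataset a
#' download hit, not which species, so each dataset's downloaded records in
#' the window are apportioned over its species proportionally to stored
#' records. This is an estimator: it preserves every dataset's download
#' total exactly and is unbiased when downloads within a dataset are
#' indifferent to species, but it cannot recover genuine species-level
#' preference within a dataset.
#'
#' @param events Bounce-filtered event tibble.
#' @param registry A `dui_registry` whose inventory has a species table.
#' @param window An [analysis_window()].
#' @param level Unit level to profile (default `"publisher"`).
#' @return Long tibble `unit_id`, `species`, `records`, `downloads`.
#' @export
species_profiles <- function(events, registry, window, level = "publisher") {
  inv <- registry$inventory
  if (is.null(inv$species)) {
    abort("the inventory has no species table; species profiles unavailable")
  }
  ev <- events[in_window(events$timestamp, window) &
                 events$event_type %in% USAGE_TYPES, ]
  dl <- tapply(ev$records_touched, ev$dataset_id, sum)

  sp <- inv$species |>
    dplyr::group_by(.data$dataset_id) |>
    dplyr::mutate(share = .data$records / sum(.data$records)) |>
    dplyr::ungroup()
  sp$downloads <- ifelse(sp$dataset_id %in% names(dl),
                         sp$share * unname(dl[sp$dataset_id]), 0)
  sp$downloads[is.na(sp$downloads)] <- 0

  units <- registry$units[registry$units$level == level, ]
  rows <- lapply(seq_len(nrow(units)), function(i) {
    members <- units$member_datasets[[i]]
    block <- sp[sp$dataset_id %in% members, ]
    if (nrow(block) == 0) return(NULL)
    block |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(records = sum(.data$records),
                       downloads = sum(.data$downloads), .groups = "drop") |>
      dplyr::mutate(unit_id = units$unit_id[i], .before = 1)
  })
  dplyr::bind_rows(rows)
}
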