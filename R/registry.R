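# Publisher size classes by dataset number N(u). The verbal ranges
# ("less than 10", "10-100", "100-300", "over 300") overlap at the decades;
# boundaries are fixed here once: 10 and 100 are medium, 300 is large.
SIZE_CLASS_BREAKS <- c(small = 0, medium = 10, large = 101, ultra_large = 301)

#' Build an analysis-unit registry from an inventory
#'
#' Registers one unit per dataset, per publisher and per country found in the
#' inventory, one unit per distinct region label when regions are given, and
#' a single world unit spanning every dataset. Units are the entities
#' indicators are computed for; each unit is simply a named set of member
#' datasets at a declared aggregation level.
#'
#' @param inventory A [dui_inventory()].
#' @return A `dui_registry`: list with `units` (tibble `unit_id`, `level`,
#'   `label`, `member_datasets` list-column) and the `inventory`.
#' @examples
#' inv <- dui_inventory(data.frame(
#'   dataset_id = c("a", "b", "c"), publisher_id = c("p1", "p1", "p2"),
#'   country_code = "DK", total_records = c(10, 20, 30)))
#' build_registry(inv)
#' @export
build_registry <- function(inventory) {
  stopifnot(inherits(inventory, "dui_inventory"))
  ds <- inventory$datasets

  unit_row <- function(id, level, members, label = id) {
    tibble::tibble(unit_id = id, level = level, label = label,
                   member_datasets = list(members))
  }

  units <- list(unit_row("world", "world", ds$dataset_id, "All registered datasets"))
  if (nrow(ds)) {
    units <- c(units,
      lapply(ds$dataset_id, function(id) unit_row(id, "dataset", id)),
      lapply(unique(ds$publisher_id), function(p) {
        unit_row(p, "publisher", ds$dataset_id[ds$publisher_id == p])
      }),
      lapply(unique(ds$country_code), function(cc) {
        unit_row(cc, "country", ds$dataset_id[ds$country_code == cc])
      }))
    regions <- unique(ds$region[!is.na(ds$region)])
    units <- c(units, lapply(regions, function(rg) {
      unit_row(rg, "region", ds$dataset_id[!is.na(ds$region) & ds$region == rg])
    }))
  }
  structure(list(units = dplyr::bind_rows(units), inventory = inventory),
            class = "dui_registry")
}

#' @export
print.dui_registry <- function(x, ...) {
  tab <- table(factor(x$units$level, levels = UNIT_LEVELS))
  cat("<dui_registry>", nrow(x$units), "units:",
      paste(sprintf("%s %s", tab[tab > 0], names(tab)[tab > 0]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Add a custom analysis unit
#'
#' Registers an extra aggregation unit (for example a species slice or an
#' ad-hoc group of publishers' datasets) on top of the automatically built
#' dataset/publisher/country/region/world units.
#'
#' @param registry A `dui_registry`.
#' @param unit_id New unit identifier (must not collide at the same level).
#' @param level One of `r paste0('"', UNIT_LEVELS, '"', collapse = ", ")`.
#' @param member_datasets Character vector of registered dataset ids.
#' @param label Display label.
#' @return The registry with the unit added.
#' @export
add_unit <- function(registry, unit_id, level, member_datasets, label = unit_id) {
  stopifnot(inherits(registry, "dui_registry"))
  level <- match.arg(level, UNIT_LEVELS)
  unknown <- setdiff(member_datasets, registry$inventory$datasets$dataset_id)
  if (length(unknown)) {
    abort(paste0("member datasets not in inventory: ", paste(unknown, collapse = ", ")))
  }
  if (any(registry$units$unit_id == unit_id & registry$units$level == level)) {
    abort(sprintf("unit '%s' already registered at level '%s'", unit_id, level))
  }
  registry$units <- dplyr::bind_rows(
    registry$units,
    tibble::tibble(unit_id = unit_id, level = level, label = label,
                   member_datasets = list(member_datasets)))
  registry
}

get_unit <- function(registry, unit_id, level = NULL) {
  stopifnot(inherits(registry, "dui_registry"))
  hits <- registry$units[registry$units$unit_id == unit_id, ]
  if (!is.null(level)) hits <- hits[hits$level == level, ]
  if (nrow(hits) == 0) abort(sprintf("unit '%s' is not registered", unit_id))
  if (nrow(hits) > 1) {
    abort(sprintf("unit id '%s' is ambiguous across levels (%s); pass `level`",
                  unit_id, paste(hits$level, collapse = ", ")))
  }
  hits
}

member_datasets <- function(registry, unit_id, level = NULL) {
  get_unit(registry, unit_id, level)$member_datasets[[1]]
}

#' Stored-record count r(u) for a unit
#'
#' The record-number denominator used throughout the indicators. When record
#' identifiers are available for every member dataset, records shared between
#' datasets are counted once (this is how a country total can be smaller than
#' the sum of its publishers' totals); otherwise the plain sum is returned
#' and the result carries attribute `dedup_unavailable = TRUE`.
#'
#' @param registry A `dui_registry`.
#' @param unit_id Unit identifier.
#' @param level Optional unit level to disambiguate ids shared across levels.
#' @param window Optional [analysis_window()]; its `record_count_convention`
#'   is recorded on the result. Inventories are single snapshots, so the
#'   convention does not change the returned number.
#' @return Numeric record count with attributes `dedup_unavailable` and
#'   `convention`.
#' @export
record_number <- function(registry, unit_id, level = NULL, window = NULL) {
  members <- member_datasets(registry, unit_id, level)
  ds <- registry$inventory$datasets
  ids_tab <- registry$inventory$record_ids
  convention <- if (!is.null(window)) window$record_count_convention else "end_of_window"

  if (length(members) == 0) {
    return(structure(0, dedup_unavailable = FALSE, convention = convention))
  }
  have_ids <- !is.null(ids_tab) && all(members %in% ids_tab$dataset_id)
  if (have_ids) {
    ids <- ids_tab$record_id[ids_tab$dataset_id %in% members]
    structure(length(unique(ids)), dedup_unavailable = FALSE, convention = convention)
  } else {
    r <- sum(ds$total_records[ds$dataset_id %in% members])
    structure(r, dedup_unavailable = length(members) > 1, convention = convention)
  }
}

#' Dataset count N(u) for a unit
#'
#' @inheritParams record_number
#' @return Integer number of member datasets.
#' @export
dataset_number <- function(registry, unit_id, level = NULL) {
  length(member_datasets(registry, unit_id, level))
}

#' Publisher size class from dataset number
#'
#' Publishers are classified by how many datasets they publish:
#' fewer than 10 is `small`, 10 to 100 is `medium`, 101 to 300 is `large`,
#' over 300 is `ultra_large`.
#'
#' @param registry A `dui_registry`.
#' @param unit_id Publisher unit id. Units at any other level are rejected.
#' @return One of `"small"`, `"medium"`, `"large"`, `"ultra_large"`.
#' @seealso [size_class_of()] for the plain count-to-class mapping.
#' @export
size_class <- function(registry, unit_id) {
  unit <- get_unit(registry, unit_id, level = NULL)
  if (unit$level != "publisher") {
    abort(sprintf("size_class is defined for publisher units; '%s' is a %s unit",
                  unit_id, unit$level))
  }
  size_class_of(length(unit$member_datasets[[1]]))
}

#' @rdname size_class
#' @param n_datasets Non-negative integer vector of dataset counts.
#' @export
size_class_of <- function(n_datasets) {
  if (any(n_datasets < 0, na.rm = TRUE)) abort("dataset counts must be non-negative")
  classes <- names(SIZE_CLASS_BREAKS)
  idx <- findInterval(n_datasets, SIZE_CLASS_BREAKS)
  out <- classes[idx]
  out[is.na(n_datasets)] <- NA_character_
  out
}
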