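#' Assemble a dataset inventory
#'
#' An inventory is the stored-records side of the usage index: one row per
#' dataset with its publisher, country and total record count, optionally a
#' long species table (stored records per species per dataset) and a table of
#' individual record identifiers (needed for exact duplicate handling and for
#' usage/interest scores).
#'
#' @param datasets Data frame with columns `dataset_id`, `publisher_id`,
#'   `country_code` and `total_records`; optional `region` and `byte_size`.
#'   Extra metadata columns are accepted and ignored.
#' @param species Optional long data frame `dataset_id`, `species`, `records`.
#'   For any dataset present here, the species records must sum to at most
#'   `total_records` (a complete species breakdown sums exactly to it).
#' @param record_ids Optional long data frame `dataset_id`, `record_id`. When
#'   present for a dataset, the number of distinct ids must equal its
#'   `total_records`.
#' @return A `dui_inventory` object: list of tibbles `datasets`, `species`,
#'   `record_ids` (the latter two possibly `NULL`).
#' @seealso [read_inventory()], [build_registry()]
#' @export
dui_inventory <- function(datasets, species = NULL, record_ids = NULL) {
  required <- c("dataset_id", "publisher_id", "country_code", "total_records")
  missing_cols <- setdiff(required, names(datasets))
  if (length(missing_cols)) {
    abort(paste0("inventory is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  datasets <- tibble::as_tibble(datasets)
  datasets$dataset_id <- as.character(datasets$dataset_id)
  datasets$publisher_id <- as.character(datasets$publisher_id)
  datasets$country_code <- as.character(datasets$country_code)
  if (!"region" %in% names(datasets)) datasets$region <- NA_character_
  if (!"byte_size" %in% names(datasets)) datasets$byte_size <- NA_real_
  datasets <- datasets[, c(required[1:3], "region", "total_records", "byte_size")]

  dup <- unique(datasets$dataset_id[duplicated(datasets$dataset_id)])
  if (length(dup)) {
    abort(paste0("duplicate dataset_id in inventory: ", paste(dup, collapse = ", ")))
  }
  if (any(is.na(datasets$total_records)) || any(datasets$total_records < 0)) {
    abort("total_records must be non-negative")
  }
  bad_cc <- !grepl("^[A-Z]{2}$", datasets$country_code)
  if (any(bad_cc)) {
    warn(paste0("country_code not ISO-3166 alpha-2 for dataset(s): ",
                paste(datasets$dataset_id[bad_cc], collapse = ", "),
                " (units still built)"))
  }

  if (!is.null(species)) {
    species <- tibble::as_tibble(species)[, c("dataset_id", "species", "records")]
    species$dataset_id <- as.character(species$dataset_id)
    species$species <- as.character(species$species)
    if (any(species$records < 0)) abort("species records must be non-negative")
    sums <- tapply(species$records, species$dataset_id, sum)
    tot <- setNames(datasets$total_records, datasets$dataset_id)
    over <- names(sums)[sums > tot[names(sums)] + 1e-9]
    if (length(over)) {
      abort(paste0("species records exceed total_records for dataset(s): ",
                   paste(over, collapse = ", ")))
    }
  }
  if (!is.null(record_ids)) {
    record_ids <- tibble::as_tibble(record_ids)[, c("dataset_id", "record_id")]
    record_ids$dataset_id <- as.character(record_ids$dataset_id)
    record_ids$record_id <- as.character(record_ids$record_id)
    n_ids <- tapply(record_ids$record_id, record_ids$dataset_id,
                    function(x) length(unique(x)))
    tot <- setNames(datasets$total_records, datasets$dataset_id)
    bad <- names(n_ids)[n_ids != tot[names(n_ids)]]
    if (length(bad)) {
      abort(paste0("record id count does not match total_records for dataset(s): ",
                   paste(bad, collapse = ", ")))
    }
  }

  structure(list(datasets = datasets, species = species, record_ids = record_ids),
            class = "dui_inventory")
}

#' @export
print.dui_inventory <- function(x, ...) {
  cat(sprintf("<dui_inventory> %d datasets, %d publishers, %d countries, %s records\n",
              nrow(x$datasets), length(unique(x$datasets$publisher_id)),
              length(unique(x$datasets$country_code)),
              format(sum(x$datasets$total_records), big.mark = ",")))
  if (!is.null(x$species)) {
    cat(sprintf("  species table: %d rows, %d distinct species\n",
                nrow(x$species), length(unique(x$species$species))))
  }
  if (!is.null(x$record_ids)) {
    cat(sprintf("  record ids available for %d dataset(s)\n",
                length(unique(x$record_ids$dataset_id))))
  }
  invisible(x)
}

#' Read a dataset inventory from CSV files
#'
#' @param datasets_csv Path to the dataset table (header `dataset_id,
#'   publisher_id,country_code,region,total_records,byte_size`; extra columns
#'   ignored).
#' @param species_csv Optional path to the long species table
#'   (`dataset_id,species,records`).
#' @param record_ids_csv Optional path to the record id table
#'   (`dataset_id,record_id`).
#' @return A [dui_inventory()] object.
#' @export
read_inventory <- function(datasets_csv, species_csv = NULL, record_ids_csv = NULL) {
  datasets <- readr::read_csv(datasets_csv, show_col_types = FALSE,
                              progress = FALSE)
  species <- if (!is.null(species_csv)) {
    readr::read_csv(species_csv, show_col_types = FALSE, progress = FALSE)
  }
  record_ids <- if (!is.null(record_ids_csv)) {
    readr::read_csv(record_ids_csv, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  dui_inventory(datasets, species = species, record_ids = record_ids)
}
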