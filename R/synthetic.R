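# Stage offsets for substream seeding: each random consumer derives its own
# seed from the root seed and a fixed label, so adding a new consumer never
# perturbs the draws of existing stages.
STAGE_OFFSETS <- c(structure_ = 101, species = 211, events = 307, timestamps = 401)

stage_seed <- function(seed, stage) {
  offset <- STAGE_OFFSETS[[stage]]
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

#' Distribution specification for the generator
#'
#' Small declarative spec for the heavy-tailed draws the generator uses.
#' Supported: `"pareto"` (continuous Pareto with floor `xmin`, shape
#' `alpha`, capped at `cap`, rounded to integers) and `"lnorm"`
#' (`meanlog`/`sdlog`, rounded, floored at 1).
#'
#' @param dist `"pareto"` or `"lnorm"`.
#' @param ... Distribution parameters (see above).
#' @return A `dist_spec` list.
#' @export
dist_spec <- function(dist = c("pareto", "lnorm"), ...) {
  dist <- match.arg(dist)
  structure(c(list(dist = dist), list(...)), class = "dist_spec")
}

draw_dist <- function(spec, n) {
  out <- switch(spec$dist,
    pareto = {
      x <- spec$xmin * runif(n)^(-1 / spec$alpha)
      if (!is.null(spec$cap)) x <- pmin(x, spec$cap)
      x
    },
    lnorm = rlnorm(n, spec$meanlog, spec$sdlog))
  pmax(1, round(out))
}

#' @rdname dist_spec
#' @param spec A `dist_spec`.
#' @return `dist_mean()`: the theoretical mean of the (capped) continuous
#'   distribution, before integer rounding.
#' @export
dist_mean <- function(spec) {
  switch(spec$dist,
    pareto = {
      a <- spec$alpha; xmin <- spec$xmin; cap <- spec$cap %||% Inf
      if (is.infinite(cap)) {
        if (a <= 1) return(Inf)
        return(a * xmin / (a - 1))
      }
      # E[min(X, cap)] for a Pareto(xmin, alpha)
      body <- if (a == 1) {
        xmin * log(cap / xmin)
      } else {
        a * xmin^a * (cap^(1 - a) - xmin^(1 - a)) / (1 - a)
      }
      body + cap * (xmin / cap)^a
    },
    lnorm = exp(spec$meanlog + spec$sdlog^2 / 2))
}

#' Configuration for the synthetic usage-log generator
#'
#' Defaults emulate the structure of a biodiversity data-portal log at desk
#' scale: a few dozen publishers whose dataset counts and dataset sizes are
#' heavy-tailed (so holdings show the long-tail concentration typical of
#' occurrence data), visitor traffic in which about two thirds of events are
#' metadata-only bounces, roughly one record-touching event in ten being a
#' download, search events retrieving a few tens of records and download
#' events a few hundred (matching observed portal search/download
#' densities), and sessions defined by the 30-minute inactivity rule.
#'
#' @param n_publishers Number of data publishers.
#' @param datasets_per_publisher [dist_spec()] for datasets per publisher.
#' @param records_per_dataset [dist_spec()] for stored records per dataset.
#' @param n_species Size of the species pool.
#' @param species_concentration Dirichlet-style concentration for allocating
#'   a dataset's records over its species (smaller = more skewed).
#' @param n_ips Number of distinct anonymized visitor keys.
#' @param events_per_ip Mean events per visitor (Poisson).
#' @param bounce_fraction Probability an event is a metadata-only bounce.
#' @param session_gap_minutes Inactivity threshold defining sessions.
#' @param download_given_search Probability a record-touching event is a
#'   download rather than a search/view.
#' @param records_per_search_event,records_per_download_event [dist_spec()]s
#'   for records touched per event (capped at the target dataset's size).
#' @param window [analysis_window()] all event timestamps fall into.
#' @param emit_record_ids Attach the full per-dataset record-id table to the
#'   generated inventory (event-level record ids are always generated).
#' @param seed Root seed; a fixed seed makes the generator byte-reproducible.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_publishers = 20,
                       datasets_per_publisher = dist_spec("pareto", xmin = 1, alpha = 0.9, cap = 30),
                       records_per_dataset = dist_spec("pareto", xmin = 40, alpha = 0.65, cap = 30000),
                       n_species = 150,
                       species_concentration = 0.3,
                       n_ips = 500,
                       events_per_ip = 20,
                       bounce_fraction = 0.66,
                       session_gap_minutes = 30,
                       download_given_search = 0.10,
                       records_per_search_event = dist_spec("lnorm", meanlog = log(25), sdlog = 0.8),
                       records_per_download_event = dist_spec("lnorm", meanlog = log(300), sdlog = 0.8),
                       window = analysis_window("2009-07-01", "2010-01-01", "2009b"),
                       emit_record_ids = FALSE,
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(bounce_fraction = bounce_fraction,
             download_given_search = download_given_search)
  if (any(probs < 0 | probs > 1)) {
    abort("bounce_fraction and download_given_search must lie in [0, 1]")
  }
  counts <- c(n_publishers = n_publishers, n_species = n_species, n_ips = n_ips)
  if (any(counts < 1)) abort("n_publishers, n_species and n_ips must be >= 1")
  if (events_per_ip <= 0) abort("events_per_ip must be positive")
  if (session_gap_minutes <= 0) abort("session_gap_minutes must be positive")
  if (species_concentration <= 0) abort("species_concentration must be positive")
  stopifnot(inherits(window, "analysis_window"))
  structure(cfg, class = "sim_config")
}

COUNTRY_POOL <- data.frame(
  country_code = c("DK", "NO", "SE", "DE", "GB", "US", "BR", "AU"),
  region = c("Europe", "Europe", "Europe", "Europe", "Europe",
             "Americas", "Americas", "Oceania"))

#' Generate a synthetic inventory and usage-event stream
#'
#' Draws a dataset inventory (publishers, datasets, per-species stored
#' records) and a visitor event log under the given configuration, together
#' with the exact per-unit counts the generator injected, so any counting
#' pipeline can be checked against ground truth rather than against itself.
#' Record identifiers are dataset-scoped (`"<dataset>:<index>"`), so
#' unique-record counts aggregate across datasets without collisions.
#'
#' @param config A [sim_config()].
#' @return List with:
#' * `inventory` — a [dui_inventory()] (species table always included),
#' * `events` — event tibble in [read_events()] layout, sorted by timestamp
#'   (bounces included, as in a raw log),
#' * `ground_truth` — tibble of injected per-unit counts (`unit_id`,
#'   `level`, `s`, `d`, `S`, `D`, `U`, `I`, `n`) for every registered unit,
#' * `registry` — the registry built from the inventory,
#' * `bounce_count` — number of bounce events emitted.
#' @export
simulate_usage <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))

  ## -- structure: publishers, datasets, stored records ---------------------
  set.seed(stage_seed(config$seed, "structure_"))
  pubs <- sprintf("PUB%02d", seq_len(config$n_publishers))
  pub_country <- COUNTRY_POOL[sample.int(nrow(COUNTRY_POOL), config$n_publishers,
                                         replace = TRUE), ]
  n_ds <- draw_dist(config$datasets_per_publisher, config$n_publishers)
  datasets <- tibble::tibble(
    dataset_id = sprintf("DS%03d", seq_len(sum(n_ds))),
    publisher_id = rep(pubs, n_ds),
    country_code = rep(pub_country$country_code, n_ds),
    region = rep(pub_country$region, n_ds),
    total_records = as.numeric(draw_dist(config$records_per_dataset, sum(n_ds))),
    byte_size = NA_real_)
  datasets$byte_size <- datasets$total_records * 512

  ## -- species allocation --------------------------------------------------
  set.seed(stage_seed(config$seed, "species"))
  species_pool <- sprintf("Species_%03d", seq_len(config$n_species))
  species_rows <- lapply(seq_len(nrow(datasets)), function(i) {
    k <- min(config$n_species, 1 + rpois(1, 4))
    sp <- sample(species_pool, k)
    w <- stats::rgamma(k, shape = config$species_concentration)
    if (sum(w) == 0) w <- rep(1, k)
    alloc <- as.vector(stats::rmultinom(1, size = datasets$total_records[i],
                                        prob = w / sum(w)))
    keep <- alloc > 0
    if (!any(keep)) return(NULL)
    tibble::tibble(dataset_id = datasets$dataset_id[i],
                   species = sp[keep], records = alloc[keep])
  })
  species <- dplyr::bind_rows(species_rows)

  record_ids <- if (isTRUE(config$emit_record_ids)) {
    tibble::tibble(
      dataset_id = rep(datasets$dataset_id, datasets$total_records),
      record_id = unlist(lapply(seq_len(nrow(datasets)), function(i) {
        paste0(datasets$dataset_id[i], ":", seq_len(datasets$total_records[i]))
      }), use.names = FALSE))
  }
  inventory <- dui_inventory(datasets, species = species, record_ids = record_ids)
  registry <- build_registry(inventory)

  ## -- events --------------------------------------------------------------
  set.seed(stage_seed(config$seed, "events"))
  n_events_ip <- rpois(config$n_ips, config$events_per_ip)
  total_events <- sum(n_events_ip)
  ip <- rep(sprintf("ip%05d", seq_len(config$n_ips)), n_events_ip)
  is_bounce <- runif(total_events) < config$bounce_fraction
  is_download <- !is_bounce & runif(total_events) < config$download_given_search
  interest_kind <- sample(c("search", "view"), total_events, replace = TRUE,
                          prob = c(0.8, 0.2))
  dl_kind <- sample(c("download", "taxonomy_download"), total_events,
                    replace = TRUE, prob = c(0.9, 0.1))
  event_type <- ifelse(is_bounce, "metadata_view",
                       ifelse(is_download, dl_kind, interest_kind))
  ds_idx <- rep(NA_integer_, total_events)
  active <- which(!is_bounce)
  if (length(active)) {
    ds_idx[active] <- sample.int(nrow(datasets), length(active), replace = TRUE,
                                 prob = datasets$total_records)
  }
  want <- rep(0, total_events)
  want[!is_bounce & !is_download] <-
    draw_dist(config$records_per_search_event, sum(!is_bounce & !is_download))
  want[is_download] <-
    draw_dist(config$records_per_download_event, sum(is_download))
  touched <- ifelse(is_bounce, 0,
                    pmin(want, datasets$total_records[ds_idx]))

  idx_lists <- vector("list", total_events)
  for (i in active) {
    idx_lists[[i]] <- sample.int(datasets$total_records[ds_idx[i]], touched[i])
  }

  set.seed(stage_seed(config$seed, "timestamps"))
  span <- as.numeric(config$window$end) - as.numeric(config$window$start)
  ts <- config$window$start + floor(runif(total_events) * span)

  events <- tibble::tibble(
    timestamp = ts,
    ip_key = ip,
    event_type = event_type,
    dataset_id = ifelse(is_bounce, NA_character_, datasets$dataset_id[ds_idx]),
    records_touched = as.integer(touched),
    record_ids = lapply(seq_len(total_events), function(i) {
      if (is.null(idx_lists[[i]])) NULL
      else paste0(datasets$dataset_id[ds_idx[i]], ":", idx_lists[[i]])
    }))
  events <- events[order(events$timestamp, events$ip_key), ]

  ## -- injected ground truth -----------------------------------------------
  ground_truth <- tally_ground_truth(
    registry, datasets$dataset_id, ds_idx, is_bounce, is_download,
    touched, idx_lists)

  list(inventory = inventory, events = events, ground_truth = ground_truth,
       registry = registry, bounce_count = sum(is_bounce))
}

# Per-unit tally of what the generator injected, computed with plain base-R
# accumulation over the generator's own internal vectors (not through the
# event-counting pipeline).
tally_ground_truth <- function(registry, dataset_ids, ds_idx, is_bounce,
                               is_download, touched, idx_lists) {
  n_ds <- length(dataset_ids)
  s <- d <- S <- D <- U <- I <- numeric(n_ds)
  dl_ids <- rep(list(integer()), n_ds)
  se_ids <- rep(list(integer()), n_ds)
  for (i in seq_along(ds_idx)) {
    if (is_bounce[i]) next
    j <- ds_idx[i]
    if (is_download[i]) {
      d[j] <- d[j] + touched[i]
      D[j] <- D[j] + 1
      dl_ids[[j]] <- c(dl_ids[[j]], idx_lists[[i]])
    } else {
      s[j] <- s[j] + touched[i]
      S[j] <- S[j] + 1
      se_ids[[j]] <- c(se_ids[[j]], idx_lists[[i]])
    }
  }
  U <- vapply(dl_ids, function(x) length(unique(x)), numeric(1))
  I <- vapply(se_ids, function(x) length(unique(x)), numeric(1))
  used <- s + d > 0 | S + D > 0

  units <- registry$units
  rows <- lapply(seq_len(nrow(units)), function(k) {
    members <- match(units$member_datasets[[k]], dataset_ids)
    tibble::tibble(
      unit_id = units$unit_id[k], level = units$level[k],
      s = sum(s[members]), d = sum(d[members]),
      S = sum(S[members]), D = sum(D[members]),
      # record ids are dataset-scoped, so unions across datasets are disjoint
      U = sum(U[members]), I = sum(I[members]),
      n = sum(used[members]))
  })
  dplyr::bind_rows(rows)
}

#' Write a simulation to portable files
#'
#' Emits the generator output in the package's file dialects:
#' `inventory.csv`, `species.csv`, `events.csv` (record ids
#' semicolon-joined, ISO-8601 timestamps) and `ground_truth.json`.
#'
#' @param sim Result of [simulate_usage()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$inventory$datasets, file.path(dir, "inventory.csv"),
                   progress = FALSE)
  readr::write_csv(sim$inventory$species, file.path(dir, "species.csv"),
                   progress = FALSE)
  ev <- sim$events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ev$record_ids <- vapply(ev$record_ids, function(x) {
    if (is.null(x)) NA_character_ else paste(x, collapse = ";")
  }, character(1))
  readr::write_csv(ev, file.path(dir, "events.csv"), na = "", progress = FALSE)
  jsonlite::write_json(sim$ground_truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
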