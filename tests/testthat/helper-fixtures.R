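# Published reference values used across the suite: raw per-unit counts for
# five unit/window columns (a large marine publisher over one month, a
# medium and a small Danish publisher plus the national aggregate over the
# second half of 2009) and the derived indicator cells printed alongside
# them.
ref_counts <- tibble::tibble(
  column = c("OBIS_Dec09", "DanBIF_09b", "HUA_09a", "HUA_09b", "DK_2009b"),
  s = c(2092927, 5682095, 2299133, 7328160, 13010255),
  d = c(555835, 854761, 809468, 717102, 1571863),
  r = c(11140298, 4995544, 259077, 259077, 4836771),
  S = c(42860, 249214, 126449, 198910, 448124),
  D = c(601, 4486, 2059, 1710, 6246),
  N = c(180, 38, 2, 2, 40),
  n = c(171, 36, 2, 2, 36))

ref_derived <- tibble::tibble(
  column = ref_counts$column,
  search_density = c(48.83, 22.80, 18.18, 36.84, 29.03),
  download_density = c(924.85, 190.54, 393.14, 407.44, 251.66),
  usage_impact = c(0.05, 0.17, 3.12, 2.77, 0.32),
  interest_impact = c(0.19, 1.14, 8.87, 28.29, 2.69),
  usage_ratio = c(0.27, 0.15, 0.35, 0.10, 0.12),
  usage_balance = c(0.014, 0.018, 0.009, 0.009, 0.014))

# Reference relative-UIF table: two datasets, their publisher, a second
# publisher, and the national aggregate they are compared against.
ref_uif <- tibble::tibble(
  unit = c("AAU_Herbarium", "AAU_PalmTransect", "HUA", "DanBIF", "Denmark"),
  r = c(110357, 148720, 259077, 4995544, 4836771),
  d = c(716772, 250330, 717102, 854761, 1571863),
  uif = c(6.50, 1.68, 2.77, 0.17, 0.32),
  rel_to_hua = c(2.35, 0.61, 1.00, NA, NA),
  rel_to_dk = c(20.31, 5.25, 8.66, 0.53, 1.00))

# Minimal inventory with two publishers in one country.
tiny_inventory <- function() {
  dui_inventory(
    data.frame(
      dataset_id = c("hua1", "hua2", paste0("dan", 1:3)),
      publisher_id = c("HUA", "HUA", "DanBIF", "DanBIF", "DanBIF"),
      country_code = "DK",
      region = "Europe",
      total_records = c(110357, 148720, 1000, 2000, 3000)))
}

# Event-row constructor with sensible defaults; `t` is minutes past an
# arbitrary origin inside the default test window.
ev <- function(t, ip = "ip1", type = "search", ds = "hua1", k = 1L, ids = NULL) {
  tibble::tibble(
    timestamp = as.POSIXct("2009-07-01 00:00:00", tz = "UTC") + t * 60,
    ip_key = ip, event_type = type, dataset_id = ds,
    records_touched = as.integer(k), record_ids = list(ids))
}

test_window <- function() analysis_window("2009-07-01", "2010-01-01", "2009b")

# Brute-force sessionization: per-ip linear scan with explicit loops,
# independent of the grouped implementation.
oracle_sessions <- function(events, gap_minutes = 30) {
  out <- list()
  for (ip in sort(unique(events$ip_key))) {
    ts <- sort(events$timestamp[events$ip_key == ip])
    idx <- 1L
    start <- ts[1]; end <- ts[1]; n <- 1L
    for (i in seq_along(ts)[-1]) {
      if (as.numeric(ts[i]) - as.numeric(ts[i - 1]) >= gap_minutes * 60) {
        out[[length(out) + 1]] <- data.frame(ip_key = ip, session_index = idx,
                                             start = start, end = end,
                                             n_events = n, loyal = idx > 1)
        idx <- idx + 1L; start <- ts[i]; n <- 0L
      }
      end <- ts[i]; n <- n + 1L
    }
    out[[length(out) + 1]] <- data.frame(ip_key = ip, session_index = idx,
                                         start = start, end = end,
                                         n_events = n, loyal = idx > 1)
  }
  do.call(rbind, out)
}

# Brute-force per-unit counting: plain loops over events.
oracle_counts <- function(events, members, window) {
  s <- d <- S <- D <- 0
  dl_ids <- character(); se_ids <- character(); used <- character()
  for (i in seq_len(nrow(events))) {
    if (events$timestamp[i] < window$start || events$timestamp[i] >= window$end) next
    if (!(events$dataset_id[i] %in% members)) next
    type <- events$event_type[i]
    if (type %in% c("search", "view")) {
      s <- s + events$records_touched[i]; S <- S + 1
      se_ids <- c(se_ids, events$record_ids[[i]])
    } else if (type %in% c("download", "taxonomy_download")) {
      d <- d + events$records_touched[i]; D <- D + 1
      dl_ids <- c(dl_ids, events$record_ids[[i]])
    } else next
    used <- c(used, events$dataset_id[i])
  }
  list(s = s, d = d, S = S, D = D,
       U = length(unique(dl_ids)), I = length(unique(se_ids)),
       n = length(unique(used)))
}

# O(n^2) pairwise-difference Gini.
oracle_gini <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}
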