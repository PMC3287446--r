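test_that("event parsing orders by timestamp and reports malformed lines", {
  raw <- tibble::tibble(
    timestamp = c("2009-07-02T10:00:00Z", "2009-07-01T09:00:00Z",
                  "not-a-time", "2009-07-03T08:00:00Z"),
    ip_key = c("a", "b", "c", "d"),
    event_type = c("search", "download", "search", "purchase"),
    dataset_id = "ds1",
    records_touched = c("5", "10", "1", "2"),
    record_ids = NA_character_)
  expect_warning(out <- parse_events(raw), "malformed")
  expect_equal(nrow(out$events), 2)
  expect_equal(out$events$ip_key, c("b", "a")) # ascending timestamps
  expect_false(is.unsorted(out$events$timestamp))
  expect_setequal(out$errors$line, c(3, 4))
  expect_match(out$errors$message[out$errors$line == 4], "event_type")
  expect_match(out$errors$message[out$errors$line == 3], "timestamp")
})

test_that("record_ids cardinality must match records_touched", {
  raw <- tibble::tibble(
    timestamp = "2009-07-01T00:00:00Z", ip_key = "a", event_type = "download",
    dataset_id = "ds1", records_touched = "3", record_ids = "r1;r2")
  expect_warning(out <- parse_events(raw), "malformed")
  expect_match(out$errors$message, "cardinality")
})

test_that("csv and jsonl logs parse to the same events", {
  rows <- dplyr::bind_rows(
    ev(0, "a", "search", "hua1", 5, c("x1", "x2", "x3", "x4", "x5")),
    ev(10, "b", "download", "hua2", 2, c("y1", "y2")),
    ev(20, "c", "metadata_view", NA, 0))
  csv <- tempfile(fileext = ".csv")
  jsonl <- tempfile(fileext = ".jsonl")
  flat <- rows
  flat$timestamp <- format(flat$timestamp, "%Y-%m-%dT%H:%M:%SZ")
  flat$record_ids <- vapply(flat$record_ids,
                            function(x) if (is.null(x)) NA_character_ else paste(x, collapse = ";"),
                            character(1))
  readr::write_csv(flat, csv, na = "")
  writeLines(vapply(seq_len(nrow(flat)), function(i) {
    jsonlite::toJSON(as.list(flat[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1)), jsonl)
  a <- read_events(csv)
  b <- read_events(jsonl)
  expect_equal(nrow(a$errors), 0)
  expect_equal(a$events, b$events)
  expect_equal(a$events$records_touched, c(5L, 2L, 0L))
  expect_equal(a$events$record_ids[[2]], c("y1", "y2"))
})

test_that("missing required columns are rejected outright", {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(data.frame(timestamp = "2009-07-01T00:00:00Z", ip_key = "a"), path)
  expect_error(read_events(path), "missing required column")
})

test_that("bounce filtering removes metadata views and zero-touch searches", {
  rows <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(1:66, function(i) ev(i, type = "metadata_view", ds = NA, k = 0))),
    dplyr::bind_rows(lapply(1:30, function(i) ev(100 + i, type = "search", k = 3))),
    dplyr::bind_rows(lapply(1:4, function(i) ev(200 + i, type = "download", k = 10))))
  out <- filter_bounces(rows)
  expect_equal(out$bounce_fraction, 0.66)
  expect_equal(nrow(out$events), 34)

  # zero-touch searches are bounces too; zero-touch downloads are kept
  mix <- dplyr::bind_rows(ev(0, type = "search", k = 0),
                          ev(1, type = "view", k = 0),
                          ev(2, type = "download", k = 0),
                          ev(3, type = "search", k = 2))
  out2 <- filter_bounces(mix)
  expect_equal(out2$bounce_fraction, 0.5)
  expect_setequal(out2$events$event_type, c("download", "search"))

  empty <- filter_bounces(rows[0, ])
  expect_equal(empty$bounce_fraction, 0)
})

test_that("bounce filtering equals an independent predicate scan on random streams", {
  set.seed(42)
  types <- sample(c("search", "view", "download", "taxonomy_download", "metadata_view"),
                  300, replace = TRUE)
  rows <- dplyr::bind_rows(lapply(seq_along(types), function(i) {
    k <- if (types[i] == "metadata_view") 0L else sample(0:5, 1)
    ev(i, ip = sample(letters, 1), type = types[i], k = k)
  }))
  keep <- logical(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    keep[i] <- !(rows$event_type[i] == "metadata_view" ||
                   (rows$event_type[i] %in% c("search", "view") &&
                      rows$records_touched[i] == 0))
  }
  out <- filter_bounces(rows)
  expect_equal(out$events, rows[keep, ])
  expect_equal(out$bounce_fraction, mean(!keep))
})

test_that("sessions split at an inactivity of exactly the gap, not below", {
  under <- dplyr::bind_rows(ev(0), ev(29), ev(58))
  s1 <- sessionize(under)
  expect_equal(nrow(s1), 1)
  expect_false(s1$loyal)

  boundary <- dplyr::bind_rows(ev(0), ev(30))
  s2 <- sessionize(boundary)
  expect_equal(nrow(s2), 2)
  expect_equal(s2$loyal, c(FALSE, TRUE))

  expect_error(sessionize(under, gap_minutes = 0), "positive")
})

test_that("sessionization matches a brute-force scan on random streams", {
  set.seed(7)
  for (rep in 1:3) {
    rows <- dplyr::bind_rows(lapply(1:400, function(i) {
      ev(runif(1, 0, 3000), ip = sprintf("ip%02d", sample.int(50, 1)))
    }))
    got <- sessionize(rows)
    want <- oracle_sessions(rows)
    got <- got[order(got$ip_key, got$start), ]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$ip_key, want$ip_key)
    expect_equal(as.numeric(got$start), as.numeric(want$start))
    expect_equal(as.numeric(got$end), as.numeric(want$end))
    expect_equal(got$n_events, want$n_events)
    expect_equal(got$loyal, want$loyal)
  }
})

test_that("sessionization ignores interleaving of distinct ip keys and is idempotent", {
  set.seed(8)
  rows <- dplyr::bind_rows(lapply(1:200, function(i) {
    ev(runif(1, 0, 2000), ip = sample(c("a", "b", "c"), 1))
  }))
  shuffled <- rows[sample.int(nrow(rows)), ]
  a <- sessionize(rows)
  b <- sessionize(shuffled)
  expect_equal(a[order(a$session_id), ], b[order(b$session_id), ])
})

test_that("per-unit counts aggregate events within the half-open window", {
  reg <- build_registry(tiny_inventory())
  w <- analysis_window("2009-07-01", "2009-08-01")
  rows <- dplyr::bind_rows(
    ev(0, "a", "search", "hua1", 5, paste0("h", 1:5)),
    ev(10, "a", "view", "hua2", 3, paste0("h", 4:6)),
    ev(20, "b", "download", "hua1", 2, paste0("h", 1:2)),
    ev(30, "b", "taxonomy_download", "hua1", 2, paste0("h", 2:3)),
    ev(40, "c", "search", "dan1", 7, paste0("d", 1:7)),           # other publisher
    ev(31 * 24 * 60, "d", "search", "hua1", 9, paste0("h", 1:9))) # outside window
  counts <- count_events(rows, reg, "HUA", w, level = "publisher")
  expect_equal(counts$s, 8)
  expect_equal(counts$S, 2)
  expect_equal(counts$d, 4)
  expect_equal(counts$D, 2)
  expect_equal(counts$U, 3) # h1,h2,h3
  expect_equal(counts$I, 6) # h1..h6
  expect_equal(counts$n, 2)

  # window end is exclusive: an event at the boundary instant is out
  at_end <- ev(31 * 24 * 60, "e", "search", "hua1", 1, "h9")
  expect_equal(count_events(at_end, reg, "HUA", w, level = "publisher")$S, 0)
  expect_equal(count_events(rows[0, ], reg, "HUA", w, level = "publisher")$s, 0)
})

test_that("unique counts are flagged unavailable when any event lacks ids", {
  reg <- build_registry(tiny_inventory())
  w <- test_window()
  rows <- dplyr::bind_rows(
    ev(0, "a", "download", "hua1", 2, c("h1", "h2")),
    ev(10, "b", "download", "hua1", 3))
  counts <- count_events(rows, reg, "HUA", w, level = "publisher")
  expect_true(is.na(counts$U))
  expect_equal(counts$d, 5)
  expect_equal(counts$I, 0) # no interest events at all: empty union
})

test_that("counts are additive over a partition of the window", {
  set.seed(9)
  reg <- build_registry(tiny_inventory())
  rows <- dplyr::bind_rows(lapply(1:300, function(i) {
    ev(runif(1, 0, 180 * 24 * 60), ip = sample(letters, 1),
       type = sample(c("search", "download"), 1),
       ds = sample(c("hua1", "hua2", "dan1"), 1), k = sample(1:5, 1))
  }))
  full <- analysis_window("2009-07-01", "2010-01-01")
  first <- analysis_window("2009-07-01", "2009-10-01")
  second <- analysis_window("2009-10-01", "2010-01-01")
  a <- count_events(rows, reg, "DK", first, level = "country")
  b <- count_events(rows, reg, "DK", second, level = "country")
  tot <- count_events(rows, reg, "DK", full, level = "country")
  for (col in c("s", "d", "S", "D")) {
    expect_equal(a[[col]] + b[[col]], tot[[col]])
  }
})

test_that("counts match a brute-force group-by on random streams", {
  set.seed(10)
  reg <- build_registry(tiny_inventory())
  w <- analysis_window("2009-07-01", "2009-09-01")
  rows <- dplyr::bind_rows(lapply(1:250, function(i) {
    k <- sample(1:4, 1)
    ev(runif(1, 0, 90 * 24 * 60), ip = sample(letters[1:5], 1),
       type = sample(c("search", "view", "download", "taxonomy_download"), 1),
       ds = sample(c("hua1", "hua2", "dan1", "dan2"), 1),
       k = k, ids = sample(sprintf("r%02d", 1:40), k))
  }))
  for (u in list(c("HUA", "publisher"), c("DK", "country"), c("hua1", "dataset"))) {
    got <- count_events(rows, reg, u[1], w, level = u[2])
    members <- reg$units$member_datasets[[which(reg$units$unit_id == u[1] &
                                                  reg$units$level == u[2])]]
    want <- oracle_counts(rows, members, w)
    for (col in names(want)) expect_equal(got[[col]], want[[col]], info = paste(u[1], col))
  }
})
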