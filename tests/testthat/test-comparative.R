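test_that("relative index is 1 against itself and matches reference values", {
  # self-relative
  expect_equal(relative_index(717102, 259077, list(d = 717102, r = 259077)), 1.0)

  dk <- list(d = 1571863, r = 4836771)
  for (i in seq_len(nrow(ref_uif))) {
    got <- relative_index(ref_uif$d[i], ref_uif$r[i], dk, mode = "rounded")
    expect_equal(round_half_up(got, 2), ref_uif$rel_to_dk[i],
                 info = ref_uif$unit[i])
  }
  hua <- list(d = 717102, r = 259077)
  for (i in 1:3) {
    got <- relative_index(ref_uif$d[i], ref_uif$r[i], hua, mode = "rounded")
    expect_equal(round_half_up(got, 2), ref_uif$rel_to_hua[i],
                 info = ref_uif$unit[i])
  }
})

test_that("rounded and full-precision modes differ where printed tables do", {
  dk <- list(d = 1571863, r = 4836771)
  herb <- c(d = 716772, r = 110357)
  expect_equal(round_half_up(relative_index(herb["d"], herb["r"], dk, mode = "rounded"), 2),
               20.31, ignore_attr = TRUE)
  expect_equal(round_half_up(relative_index(herb["d"], herb["r"], dk, mode = "full"), 2),
               19.99, ignore_attr = TRUE)
})

test_that("the r-weighted mean of member relative indices equals 1 (ratio of sums)", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(3:12, 1)
    members <- data.frame(d = sample(1:100000, n), r = sample(100:100000, n))
    idx <- vapply(seq_len(n), function(i) {
      relative_index(members$d[i], members$r[i], members)
    }, numeric(1))
    expect_equal(sum(members$r * idx) / sum(members$r), 1.0, tolerance = 1e-9)
  }
})

test_that("a zero-record baseline is undefined, not infinite", {
  expect_warning(out <- relative_index(10, 100, list(d = 0, r = 0)), "zero stored")
  expect_true(is.na(out))
  expect_warning(out2 <- relative_index(10, 100, list(d = 0, r = 50)), "zero")
  expect_true(is.na(out2))
})

test_that("species baseline is the ratio of sums over reference units", {
  profiles <- data.frame(
    unit_id = c("u1", "u2"), species = "X",
    records = c(100, 100), downloads = c(10, 0))
  base <- species_baseline(profiles)
  expect_equal(base$expected_uif[base$species == "X"], 0.05) # (10+0)/(100+100)
  expect_equal(attr(base, "n_units"), 2)

  # single reference unit: baseline equals that unit's own per-species UIF
  one <- data.frame(unit_id = "u1", species = c("A", "B"),
                    records = c(50, 200), downloads = c(5, 100))
  b1 <- species_baseline(one)
  expect_equal(b1$expected_uif[match(c("A", "B"), b1$species)], c(0.1, 0.5))

  # constant field: every species inherits the common rate
  const <- data.frame(unit_id = rep(c("u1", "u2"), each = 2),
                      species = rep(c("A", "B"), 2),
                      records = c(10, 20, 30, 40))
  const$downloads <- const$records * 0.2
  bc <- species_baseline(const)
  expect_equal(bc$expected_uif, rep(0.2, 2))

  # zero-record species are omitted with a warning, not set to zero
  withz <- rbind(profiles, data.frame(unit_id = "u3", species = "GHOST",
                                      records = 0, downloads = 0))
  expect_warning(bz <- species_baseline(withz), "GHOST")
  expect_false("GHOST" %in% bz$species)
})

test_that("crown indicator is 1 for the union of the reference units", {
  set.seed(22)
  for (rep in 1:5) {
    n_units <- sample(2:6, 1)
    n_sp <- sample(2:8, 1)
    profiles <- expand.grid(unit_id = sprintf("u%d", seq_len(n_units)),
                            species = sprintf("s%d", seq_len(n_sp)),
                            stringsAsFactors = FALSE)
    profiles$records <- sample(1:5000, nrow(profiles))
    profiles$downloads <- round(runif(nrow(profiles)) * 2000)
    base <- species_baseline(profiles)
    world <- profiles |>
      dplyr::group_by(species) |>
      dplyr::summarise(records = sum(records), downloads = sum(downloads))
    expect_equal(usage_crown_indicator(world, base), 1.0, tolerance = 1e-12)
  }
})

test_that("crown indicator reduces to UIF over global species UIF for one species", {
  base <- data.frame(species = "X", expected_uif = 0.04)
  prof <- data.frame(species = "X", records = 500)
  uci <- usage_crown_indicator(prof, base, d_total = 60)
  expect_equal(uci, (60 / 500) / 0.04)
})

test_that("crown indicator matches a hand-computed expected-download table", {
  # three units, two species, asymmetric download rates
  profiles <- data.frame(
    unit_id = rep(c("u1", "u2", "u3"), each = 2),
    species = rep(c("A", "B"), 3),
    records = c(100, 300, 200, 100, 700, 600),
    downloads = c(20, 3, 10, 2, 70, 15))
  base <- species_baseline(profiles)
  # expected per-species global UIF: A: 100/1000 = 0.1, B: 20/1000 = 0.02
  expect_equal(base$expected_uif[match(c("A", "B"), base$species)], c(0.1, 0.02))
  prof_u1 <- profiles[profiles$unit_id == "u1", ]
  # expected downloads for u1: 100*0.1 + 300*0.02 = 16; observed 23
  expect_equal(usage_crown_indicator(prof_u1, base), 23 / 16)
})

test_that("crown indicator is invariant to uniform scaling of all downloads", {
  profiles <- data.frame(
    unit_id = rep(c("u1", "u2"), each = 2),
    species = rep(c("A", "B"), 2),
    records = c(10, 40, 90, 60),
    downloads = c(4, 2, 18, 3))
  base <- species_baseline(profiles)
  prof <- profiles[profiles$unit_id == "u1", ]
  uci1 <- usage_crown_indicator(prof, base)
  scaled <- profiles
  scaled$downloads <- scaled$downloads * 13
  base13 <- species_baseline(scaled)
  prof13 <- scaled[scaled$unit_id == "u1", ]
  expect_equal(usage_crown_indicator(prof13, base13), uci1, tolerance = 1e-12)
})

test_that("profile species missing from the baseline are an error listing them", {
  base <- data.frame(species = "A", expected_uif = 0.1)
  prof <- data.frame(species = c("A", "Q", "Z"), records = c(10, 5, 5),
                     downloads = c(1, 1, 1))
  expect_error(usage_crown_indicator(prof, base), "Q, Z")
})

test_that("an all-zero expected-download profile is undefined", {
  base <- data.frame(species = "A", expected_uif = 0)
  prof <- data.frame(species = "A", records = 10)
  expect_warning(out <- usage_crown_indicator(prof, base, d_total = 5), "undefined")
  expect_true(is.na(out))
})

test_that("brute-force size adjustment rescales by records in millions", {
  expect_equal(brute_force_adjust(0.171105, 4995544), 0.171105 * 4.995544)
  expect_equal(brute_force_adjust(2.5, 1e6), 2.5)
  expect_equal(brute_force_adjust(3.7, 0), 0)
  # algebraic identity: UIF * r/1e6 = d/1e6
  d <- 854761; r <- 4995544
  expect_equal(brute_force_adjust(d / r, r), d / 1e6, tolerance = 1e-12)
})

test_that("apportioned species profiles preserve dataset download totals", {
  ds <- data.frame(dataset_id = c("d1", "d2"), publisher_id = c("p1", "p2"),
                   country_code = "DK", total_records = c(100, 50))
  sp <- data.frame(dataset_id = c("d1", "d1", "d2"),
                   species = c("A", "B", "A"),
                   records = c(75, 25, 50))
  reg <- build_registry(dui_inventory(ds, species = sp))
  w <- test_window()
  rows <- dplyr::bind_rows(
    ev(0, "a", "download", "d1", 40, NULL),
    ev(10, "b", "download", "d2", 10, NULL),
    ev(20, "c", "search", "d1", 5, NULL))
  prof <- species_profiles(rows, reg, w, level = "publisher")
  p1 <- prof[prof$unit_id == "p1", ]
  expect_equal(sum(p1$downloads), 40) # dataset total preserved
  expect_equal(p1$downloads[p1$species == "A"], 30) # 40 * 75/100
  expect_equal(p1$downloads[p1$species == "B"], 10)
  world <- species_profiles(rows, reg, w, level = "world")
  expect_equal(sum(world$downloads), 50)
  expect_equal(world$records[world$species == "A"], 125)
})
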