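test_that("read_detections parses, sorts and logs rejects", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,transmitter_id,receiver_id",
    "2014-05-02T08:30:00,T1,R1",
    "2014-05-01T23:59:59,T2,R2",
    "2014-05-02T00:00:01,T1,R2"
  ), f)
  det <- read_detections(f)
  expect_equal(nrow(det), 3)
  expect_false(is.unsorted(det$timestamp))
  expect_equal(det$transmitter_id, c("T2", "T1", "T1"))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,transmitter_id,receiver_id",
    "2014-05-02T08:30:00,T1,R1",
    "2014-05-02T09:30:00,,R1",
    "2014-05-02T10:30:00,T2,R1"
  ), f2)
  expect_message(det2 <- read_detections(f2), "rejected 1 of 3")
  expect_equal(nrow(det2), 2)
  expect_equal(attr(det2, "rejects")$reason, "blank_identifier")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,transmitter_id,receiver_id", "x,y,z"), f3)
  expect_error(read_detections(f3), "missing required column")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,transmitter_id,receiver_id",
               "not-a-time,T1,R1", "2014-05-02T08:30:00,T1,R1"), f4)
  expect_error(read_detections(f4), "unparseable timestamps")
})

test_that("detection log round-trips through CSV with the generator's tally", {
  sc <- quick_scenario(seed = 42)
  sim <- simulate_detections(sc)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    dplyr::mutate(sim$detections,
                  timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%S")), f)
  det <- read_detections(f)
  expect_equal(nrow(det), nrow(sim$detections))
  expect_equal(sort(unique(det$transmitter_id)),
               sort(unique(sim$detections$transmitter_id)))
})

test_that("region assignment uses half-open longitude intervals", {
  breaks <- c(25.70, 25.95)
  expect_equal(assign_region(c(25.69, 25.70, 25.94, 25.95, 26.2), breaks),
               c("west", "central", "central", "east", "east"))
})

test_that("receiver validation enforces enum, uniqueness and date order", {
  rec <- toy_receivers(5)
  expect_error(validate_receivers(dplyr::mutate(rec, zone = "river")),
               "invalid zone")
  expect_error(validate_receivers(rec[c(1, 1, 2), ]), "duplicate receiver_id")
  bad <- dplyr::mutate(rec, active_end = active_start)
  expect_error(validate_receivers(bad), "active_start must precede")
})

test_that("simulated receiver regions survive a CSV round trip", {
  sc <- quick_scenario(seed = 3)
  sim <- simulate_detections(sc)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(sim$receivers, -region), f)
  rec <- read_receivers(f)
  expect_equal(rec$region, sim$receivers$region)
})

test_that("monitoring_end is the earliest live candidate", {
  base <- tibble::tibble(
    tag_date = as.Date("2015-01-01"),
    study_end = as.Date("2020-12-31"),
    battery_expiry = as.Date("2018-06-01"),
    recapture_date = as.Date(NA),
    last_outside_detection = as.Date(NA)
  )
  expect_equal(monitoring_end(base), as.Date("2018-06-01"))

  recap <- dplyr::mutate(base, recapture_date = tag_date + 60,
                         battery_expiry = tag_date + 3 * 365)
  expect_equal(monitoring_end(recap), recap$tag_date + 60)

  # brute-force enumeration over all subsets of present candidates
  cands <- list(
    study_end = as.Date("2019-05-05"),
    battery_expiry = as.Date("2017-08-09"),
    recapture_date = as.Date("2018-01-02"),
    last_outside_detection = as.Date("2016-11-30")
  )
  for (mask in 1:15) {
    present <- names(cands)[bitwAnd(mask, c(1, 2, 4, 8)) > 0]
    if (!all(c("study_end", "battery_expiry") %in% present)) next
    row <- tibble::tibble(tag_date = as.Date("2015-01-01"),
                          study_end = as.Date(NA),
                          battery_expiry = as.Date(NA),
                          recapture_date = as.Date(NA),
                          last_outside_detection = as.Date(NA))
    for (p in present) row[[p]] <- cands[[p]]
    expect_equal(monitoring_end(row),
                 min(do.call(c, cands[present])))
  }

  bad <- dplyr::mutate(base, recapture_date = as.Date("2014-01-01"))
  expect_error(monitoring_end(bad), "precedes tag_date")
})

test_that("filter_dataset applies the 10-day rule with an inclusive boundary", {
  rec <- toy_receivers(3)
  tags <- toy_tags(c("A", "B", "C"))
  mk <- function(id, dates) {
    tibble::tibble(timestamp = ts(paste(dates, "12:00:00")),
                   transmitter_id = id, receiver_id = "R1")
  }
  det <- dplyr::bind_rows(
    mk("A", as.Date("2014-02-01") + 0:8),    # 9 days -> excluded
    mk("B", as.Date("2014-02-01") + 0:9),    # 10 days -> retained
    mk("C", as.Date("2014-02-01") + 0:20)    # 21 days -> retained
  )
  ds <- filter_dataset(det, tags, rec, min_days = 10)
  expect_setequal(ds$tags$transmitter_id, c("B", "C"))
  expect_equal(ds$exclusions$transmitter_id, "A")
  expect_equal(ds$exclusions$reason, "below_min_days")
})

test_that("estuary receivers, unknown tags and out-of-window rows are removed", {
  rec <- dplyr::bind_rows(toy_receivers(2),
                          dplyr::mutate(toy_receivers(1), receiver_id = "E1",
                                        zone = "estuary"))
  tags <- toy_tags("A", tag_date = as.Date("2014-06-01"))
  tags$battery_expiry <- as.Date("2014-12-31")
  tags <- validate_tags(dplyr::select(tags, -monitoring_end, -study_end),
                        study_end = as.Date("2016-12-31"))
  det <- tibble::tibble(
    timestamp = ts(c("2014-06-10 10:00:00", "2014-06-11 10:00:00",
                     "2014-05-01 10:00:00",   # before tagging
                     "2015-02-01 10:00:00",   # after battery expiry
                     "2014-06-12 10:00:00",   # estuary receiver
                     "2014-06-13 10:00:00")), # unknown transmitter
    transmitter_id = c("A", "A", "A", "A", "A", "ZZZ"),
    receiver_id = c("R1", "R2", "R1", "R1", "E1", "R1")
  )
  expect_message(ds <- filter_dataset(det, tags, rec, min_days = 1),
                 "unknown transmitters")
  expect_equal(nrow(ds$detections), 2)
  expect_true(all(ds$detections$receiver_id %in% c("R1", "R2")))
  expect_true(all(ds$detections$date >= as.Date("2014-06-01") &
                    ds$detections$date <= as.Date("2014-12-31")))
  expect_error(filter_dataset(det, tags, rec, min_days = 100),
               "no individuals retained")
})

test_that("filtering is idempotent and exclusions partition the cohort", {
  sc <- quick_scenario(seed = 11, base_prob = c(0.05, 0.3),
                       n_per_species = 8L)
  sim <- simulate_detections(sc)
  ds1 <- suppressMessages(filter_dataset(sim$detections, sim$tags,
                                         sim$receivers))
  ds2 <- suppressMessages(filter_dataset(ds1$detections, ds1$tags,
                                         ds1$receivers))
  expect_equal(ds2$detections, ds1$detections)
  expect_equal(ds2$tags$transmitter_id, ds1$tags$transmitter_id)
  expect_equal(nrow(ds2$exclusions), 0)
  # retained + excluded = tagged, no overlap
  expect_setequal(c(ds1$tags$transmitter_id, ds1$exclusions$transmitter_id),
                  sim$tags$transmitter_id)
  expect_length(intersect(ds1$tags$transmitter_id,
                          ds1$exclusions$transmitter_id), 0)
  # retained set matches the generator's truth at the same threshold
  truth_days <- dplyr::count(sim$truth$detection_days, transmitter_id)
  should_keep <- truth_days$transmitter_id[truth_days$n >= 10]
  expect_setequal(ds1$tags$transmitter_id, should_keep)
})

test_that("no retained detection violates window or zone invariants", {
  sc <- quick_scenario(seed = 5)
  sim <- simulate_detections(sc)
  ds <- suppressMessages(filter_dataset(sim$detections, sim$tags,
                                        sim$receivers))
  joined <- dplyr::left_join(
    ds$detections,
    dplyr::select(ds$tags, transmitter_id, tag_date, monitoring_end),
    by = "transmitter_id")
  expect_true(all(joined$date >= joined$tag_date))
  expect_true(all(joined$date <= joined$monitoring_end))
  expect_true(all(ds$detections$receiver_id %in%
                    ds$receivers$receiver_id[ds$receivers$zone == "marine"]))
})

test_that("cohort summary reproduces printed-style percentages", {
  rec <- toy_receivers(2)
  # 13 tagged subadults with 7 retained; 10 tagged adults with 9 retained
  tags <- dplyr::bind_rows(
    toy_tags(sprintf("S%02d", 1:13), species = "L_amia",
             life_stage = "subadult"),
    toy_tags(sprintf("A%02d", 1:10), species = "L_amia", life_stage = "adult")
  )
  keep <- c(sprintf("S%02d", 1:7), sprintf("A%02d", 1:9))
  det <- tidyr::expand_grid(transmitter_id = keep, d = 0:11) |>
    dplyr::mutate(timestamp = ts(paste(as.Date("2014-03-01") + d, "10:00:00")),
                  receiver_id = "R1") |>
    dplyr::select(timestamp, transmitter_id, receiver_id)
  ds <- filter_dataset(det, tags, rec, min_days = 10)
  cs <- cohort_summary(ds, tags)
  expect_equal(cs$pct_retained[cs$life_stage == "subadult"], 54L)
  expect_equal(cs$pct_retained[cs$life_stage == "adult"], 90L)
  overall <- cs[cs$species == "all", ]
  expect_equal(overall$n_tagged, 23L)
  expect_equal(overall$n_retained, 16L)
  expect_equal(sum(cs$n_tagged[cs$species != "all"]), nrow(tags))
  expect_equal(pct_round(16, 16), 100L)
})
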