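test_that("MET histogram has nine 1.5-MET bins with category roll-ups", {
  h <- build_met_histogram(make_epochs(0))
  expect_identical(nrow(h), 9L)
  inner <- h[-c(1, 9), ]
  expect_true(all(inner$met_high - inner$met_low == 1.5))
  expect_equal(h$category,
               c("stationary", "light", "moderate", "moderate", "vigorous",
                 "vigorous", "very_vigorous", "very_vigorous", "very_vigorous"))

  # direct placement: MET 1.0, 2.0 and 13.0 land in bins 1, 2 and 9
  ep <- make_epochs(3, mad_mg = c(0, 50, 600), madxyz_mg = c(0, 60, 1400))
  expect_equal(round(ep$met, 3), c(1, 2.115, 15.383))
  h2 <- build_met_histogram(ep)
  expect_equal(h2$minutes, c(0.1, 0.1, 0, 0, 0, 0, 0, 0, 0.1))
  expect_equal(sum(build_met_histogram(make_epochs(0))$minutes), 0)
})

test_that("sleep-log epochs are excluded from behavior summaries", {
  start <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  ep <- make_epochs(600, start = start, mad_mg = 10, ape_deg = 20)
  sl <- sleep_log(format(start), format(start + 300))  # first 50 epochs asleep
  h <- build_met_histogram(ep, sleep = sl)
  expect_equal(sum(h$minutes), (600 - 50) * 0.1)
})

test_that("day validity requires complete wear and 10 reference settings", {
  d_ok <- assess_day_validity(make_day(settings = 12))
  expect_true(d_ok$valid)
  expect_equal(d_ok$wear_min, 1440)
  d_few <- assess_day_validity(make_day(settings = 9))
  expect_false(d_few$valid)
  # 20 h of wear fails regardless of settings
  ep <- make_day(settings = 30)
  ep$wear[1:2400] <- FALSE
  ep$stationary[1:2400] <- FALSE
  ep$ape_deg[1:2400] <- NA
  d_short <- assess_day_validity(ep)
  expect_false(d_short$valid)
  expect_equal(d_short$wear_min, 1200)
  # the wear tolerance admits a four-minute gap by default
  ep2 <- make_day(settings = 12)
  ep2$wear[1:40] <- FALSE
  expect_true(assess_day_validity(ep2)$valid)
  ep2$wear[1:50] <- FALSE
  expect_false(assess_day_validity(ep2)$valid)
})

test_that("daily minutes are conserved across MET bins and postures", {
  day <- make_day(settings = 12)
  s <- assess_day_validity(day)
  met_cols <- paste0("met_min_", 1:9)
  expect_equal(sum(s[, met_cols]), s$wear_min)  # awake wear = all wear here
  ape_cols <- paste0("ape_min_", 1:18)
  expect_equal(sum(s[, ape_cols]), s$stationary_min)
  expect_equal(s$standing_min + s$sitting_min + s$reclining_min + s$lying_min,
               s$stationary_min)
})

test_that("participants need at least four valid days; means use valid days", {
  mk_days <- function(valid) {
    data.frame(date = as.Date("2024-03-04") + seq_along(valid) - 1,
               wear_min = 1440, settings = 12, valid = valid,
               stationary_min = 700, met_min_1 = ifelse(valid, 100, 999))
  }
  expect_true(select_participant(mk_days(rep(TRUE, 4)))$included)
  expect_false(select_participant(mk_days(c(TRUE, TRUE, TRUE, FALSE,
                                            FALSE, FALSE)))$included)
  p <- select_participant(mk_days(rep(TRUE, 7)))
  expect_equal(unname(p$mean_minutes["met_min_1"]), 100)
  # monotonicity: adding a valid day never flips inclusion off
  base <- mk_days(c(TRUE, TRUE, TRUE, TRUE, FALSE))
  more <- rbind(base, mk_days(TRUE))
  expect_true(select_participant(base)$included)
  expect_true(select_participant(more)$included)
})

test_that("hourly profile splits stationary time at 30 degrees per clock hour", {
  start <- as.POSIXct("2024-03-04 11:00:00", tz = "UTC")  # a Monday
  ep <- make_epochs(10, start = start, ape_deg = 20)
  prof <- hourly_stationary_profile(ep, weekend = FALSE)
  expect_equal(prof$lt_min[prof$hour == 11], 1.0)
  expect_equal(sum(prof$ge_min), 0)
  # the 30-degree boundary counts as the upper split
  ep30 <- make_epochs(10, start = start, ape_deg = 30)
  prof30 <- hourly_stationary_profile(ep30, weekend = FALSE)
  expect_equal(prof30$ge_min[prof30$hour == 11], 1.0)
  expect_equal(sum(prof30$lt_min), 0)
  # weekend filter: a Monday contributes nothing to the weekend profile
  expect_equal(sum(hourly_stationary_profile(ep, weekend = TRUE)$lt_min), 0)
  # no stationary epochs: zero profile
  none <- make_epochs(10, start = start, mad_mg = 100, ape_deg = NA)
  expect_equal(sum(hourly_stationary_profile(none)$lt_min +
                     hourly_stationary_profile(none)$ge_min), 0)
  # averaging across two days of the same type
  ep2 <- rbind(ep, make_epochs(30, start = start + 86400, ape_deg = 40))
  prof2 <- hourly_stationary_profile(ep2, weekend = FALSE)
  expect_equal(prof2$lt_min[prof2$hour == 11], 0.5)
  expect_equal(prof2$ge_min[prof2$hour == 11], 1.5)
})
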