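test_that("orientation vectors normalize and flag zero norms", {
  expect_equal(orientation_vector(c(0, 0, 1)), c(0, 0, 1))
  expect_equal(orientation_vector(c(0, 0, 2)), c(0, 0, 1))
  expect_equal(orientation_vector(c(1, 1, 0)), c(sqrt(2) / 2, sqrt(2) / 2, 0))
  expect_warning(v <- orientation_vector(c(0, 0, 0)), "zero-norm")
  expect_true(all(is.na(v)))
})

test_that("walking recognition applies all three criteria with strict ratio", {
  expect_true(is_walking_reference(250, 10, 300))    # ratio 1.2
  expect_false(is_walking_reference(400, 10, 480))   # MAD out of range
  expect_false(is_walking_reference(250, 10, 400))   # ratio exactly 1.6: fails
  expect_true(is_walking_reference(250, 10, 399))    # just under 1.6
  expect_false(is_walking_reference(250, 7, 300))    # too few steps
  expect_false(is_walking_reference(250, 14, 300))   # too many steps
  expect_true(all(is_walking_reference(c(150, 350), c(8, 13), c(150, 350))))
})

test_that("reference tracking is last-setting-wins with optional backfill", {
  ep <- make_epochs(10, mad_mg = 10, ape_deg = NA)
  # no walking epoch: all references undefined
  tr <- track_reference(ep[, setdiff(names(ep), c("ux", "uy", "uz",
                                                  "is_reference"))])
  expect_true(all(is.na(tr$ux)))
  expect_identical(nrow(attr(tr, "settings_log")), 0L)

  # one walking epoch at position 4: epochs 4..10 carry its orientation
  ep$mad_mg[4] <- 250; ep$madxyz_mg[4] <- 300; ep$steps[4] <- 10L
  ep$xave_g[4] <- 0.1; ep$zave_g[4] <- 0.995
  tr <- track_reference(ep[, setdiff(names(ep), c("ux", "uy", "uz",
                                                  "is_reference"))])
  expect_true(all(is.na(tr$ux[1:3])))
  expect_equal(tr$ux[4:10], rep(0.1 / sqrt(0.1^2 + 0.995^2), 7))
  tr_bf <- track_reference(ep[, setdiff(names(ep), c("ux", "uy", "uz",
                                                     "is_reference"))],
                           backfill = TRUE)
  expect_equal(tr_bf$ux[1], tr_bf$ux[4])
})

test_that("a new reference setting changes the APE of a fixed posture", {
  # scripted two-orientation trace: the same desk posture reads 20 deg against
  # an upright walking reference, then 10 deg after a tilted walking bout
  # (e.g. the belt shifted) resets the reference
  sch <- activity_schedule(c(60, 120, 60, 120),
                           c("walking", "desk_sitting",
                             "walking", "desk_sitting"),
                           tilt_deg = c(0, 20, 10, 20), noise_mg = 0)
  g <- generate_recording(sch, sampling_rate = 20, quantize = FALSE)
  ep <- annotate_postures(track_reference(compute_epochs(g$recording)))
  ape <- ep$ape_deg
  desk1 <- which(g$truth$activity == "desk_sitting" & g$truth$epoch <= 30)
  desk2 <- which(g$truth$activity == "desk_sitting" & g$truth$epoch > 30)
  expect_equal(median(ape[desk1]), 20, tolerance = 0.05)
  expect_equal(median(ape[desk2]), 10, tolerance = 0.05)
})

test_that("APE is the clamped arccos of the inner product, in degrees", {
  u <- c(0, 0, 1)
  expect_equal(compute_ape(u, u), 0)
  expect_equal(compute_ape(c(1, 0, 0), u), 90)
  expect_equal(compute_ape(c(0, 0, 1), c(0, sqrt(2) / 2, sqrt(2) / 2)), 45)
  expect_equal(compute_ape(c(0, 0, -1), u), 180)
  # rounding outside [-1, 1] is absorbed
  v <- c(0, 0, 1 + 1e-14)
  expect_equal(compute_ape(v, u), 0)
  expect_true(all(compute_ape(matrix(rnorm(30), 10, 3) |>
                                orientation_vector(), u) |>
                    (\(x) x >= 0 & x <= 180)()))
})

test_that("posture cut-points are 11.6 / 30 / 73.9 with inclusive lower bounds", {
  expect_equal(as.character(classify_posture(c(0, 8, 11.59))),
               rep("standing", 3))
  expect_equal(as.character(classify_posture(c(11.6, 20, 29.99))),
               rep("sitting", 3))
  expect_equal(as.character(classify_posture(c(30, 45, 73.89))),
               rep("reclining", 3))
  expect_equal(as.character(classify_posture(c(73.9, 80, 180))),
               rep("lying", 3))
  expect_true(is.na(classify_posture(NA_real_)))
  expect_error(classify_posture(10, cutpoints = c(30, 11.6, 73.9)),
               "config error")
})

test_that("APE histogram has 18 five-degree bins that conserve minutes", {
  ep <- make_epochs(3, ape_deg = c(2, 7, 87))
  h <- build_ape_histogram(ep)
  expect_identical(nrow(h), 18L)
  expect_equal(h$bin_low_deg, seq(0, 85, by = 5))
  expect_equal(h$minutes[c(1, 2, 18)], rep(0.1, 3))
  expect_equal(sum(h$minutes), 0.3)

  one <- build_ape_histogram(make_epochs(1, ape_deg = 3))
  expect_equal(one$minutes, c(0.1, rep(0, 17)))
  empty <- build_ape_histogram(make_epochs(4, mad_mg = 100, ape_deg = NA))
  expect_equal(sum(empty$minutes), 0)
  # the descriptive annotations follow the published bin mapping
  expect_equal(h$annotation[1:2], rep("standing", 2))
  expect_equal(h$annotation[16:18], rep("lying", 3))
})

test_that("histogram minutes and epoch-level posture labels agree", {
  set.seed(13)
  ape <- runif(400, 0, 100)
  ep <- make_epochs(400, ape_deg = ape)
  h <- build_ape_histogram(ep)
  expect_equal(sum(h$minutes), 40)                     # conservation: 0.1 min each
  standing_min <- sum(ep$posture == "standing") * 0.1
  # standing = bins below 10 plus the part of [10, 15) under 11.6
  expect_equal(standing_min,
               sum(h$minutes[1:2]) + sum(ape >= 10 & ape < 11.6) * 0.1)
})
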