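test_that("distance accumulates path length in meters", {
  expect_equal(distance_traveled(linear_track(0, 137, duration_s = 60)), 1.37,
               tolerance = 1e-9)

  # out and back: two traversals
  n <- 900
  x <- c(seq(0, 137, length.out = n / 2), seq(137, 0, length.out = n / 2))
  tr <- animal_track(data.frame(time_s = (seq_len(n) - 1) / 15, x_cm = x),
                     "back", fps = 15)
  # smoothing off: the median filter would clip the turning point itself
  expect_equal(distance_traveled(tr, smoothing_window_frames = 0), 2.74,
               tolerance = 1e-6)

  expect_equal(distance_traveled(stationary_track(30)), 0)
  expect_error(distance_traveled(stationary_track(30), window = c(0, 0.05)),
               class = "tgt_empty_window_error")
})

test_that("distance ignores time origin and appended stationary frames", {
  tr <- linear_track(10, 100, duration_s = 30)
  d0 <- distance_traveled(tr)

  shifted <- tr
  shifted$samples$time_s <- shifted$samples$time_s + 120
  expect_equal(distance_traveled(animal_track(shifted$samples, "s", 15),
                                 window = c(120, 151)), d0)

  n0 <- nrow(tr$samples)
  extra <- data.frame(time_s = tr$samples$time_s[n0] + (1:150) / 15,
                      x_cm = rep(tr$samples$x_cm[n0], 150))
  padded <- animal_track(rbind(tr$samples, extra), "p", 15)
  expect_equal(distance_traveled(padded), d0, tolerance = 1e-9)
})

test_that("immobility bouts follow the strict >3 s convention", {
  # fully stationary 570 s window: one bout covering everything
  still <- stationary_track(30, duration_s = 570)
  bouts <- detect_immobility_bouts(still)
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$duration_s, 570)
  summ <- resting_summary(still, bouts)
  expect_equal(summ$resting_percent, 100)

  # constant 5 cm/s never dips under a 0.5 cm/s threshold
  moving <- linear_track(0, 137, duration_s = 137 / 5)
  expect_equal(nrow(detect_immobility_bouts(moving, 0.5)), 0)

  expect_error(detect_immobility_bouts(still, speed_threshold_cm_s = 0),
               class = "tgt_config_error")
})

test_that("an embedded stop is recovered as a single bout of the right length", {
  fps <- 15
  seg1 <- seq(0, 50, by = 5 / fps)           # 5 cm/s approach
  stop_frames <- rep(50, 5 * fps)            # 5 s stop
  seg2 <- seq(50, 100, by = 5 / fps)[-1]     # resume
  x <- c(seg1, stop_frames, seg2)
  tr <- animal_track(data.frame(time_s = (seq_along(x) - 1) / fps, x_cm = x),
                     "stop", fps = fps)
  bouts <- detect_immobility_bouts(tr, 0.5, min_bout_s = 3,
                                   smoothing_window_frames = 0)
  expect_equal(nrow(bouts), 1)
  expect_lt(abs(bouts$duration_s - 5), 1 / fps + 1e-9)
  expect_equal(bouts$zone, zone_of_position(50))
})

test_that("bout lists are strict, ordered and non-overlapping", {
  for (s in 1:3) {
    tr <- preprocess(simulate_track(simulation_config(
      rest_hazard_per_s = 0.2, rest_mean_s = 5, duration_s = 300, seed = 80 + s)),
      preprocess_spec(exclude_initial_s = 0, analysis_window_s = 300))
    bouts <- detect_immobility_bouts(tr)
    if (!nrow(bouts)) next
    expect_true(all(bouts$duration_s > 3.0))
    if (nrow(bouts) > 1) {
      ends <- bouts$start_s + bouts$duration_s
      expect_true(all(bouts$start_s[-1] >= ends[-nrow(bouts)] - 1e-9))
    }
  }
})

test_that("resting decomposition over zones is conserved", {
  tr <- preprocess(simulate_track(simulation_config(
    rest_hazard_per_s = 0.3, rest_mean_s = 6, duration_s = 600, seed = 91)))
  summ <- resting_summary(tr)
  expect_equal(sum(summ$resting_percent_by_zone), summ$resting_percent,
               tolerance = 1e-9)
  expect_true(summ$resting_percent >= 0 && summ$resting_percent <= 100)

  none <- resting_summary(linear_track(0, 137, duration_s = 137 / 5))
  expect_equal(none$resting_percent, 0)
  expect_equal(none$resting_percent_by_zone, rep(0, 14))
})

test_that("resting concentrates where occupancy concentrates", {
  # rest hazard is weighted toward the preferred temperature, so the
  # resting-by-zone distribution should track the occupancy profile
  ok <- 0
  for (s in 1:10) {
    co <- simulate_cohort("naive_male", n_animals = 12, seed = 500 + s)
    pre <- lapply(co$tracks, preprocess)
    occ <- colMeans(do.call(rbind, lapply(pre, function(t)
      occupancy_profile(t)$percent_by_zone)))
    rest <- colSums(do.call(rbind, lapply(pre, function(t)
      resting_summary(t)$resting_percent_by_zone)))
    if (stats::cor(occ, rest, method = "spearman") > 0.8) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("condition presets order cohort locomotion as expected", {
  mean_dist <- function(name, seed) {
    co <- simulate_cohort(name, n_animals = 6, seed = seed)
    mean(vapply(co$tracks, function(t) distance_traveled(preprocess(t)), 0))
  }
  for (seed in c(1, 2)) {
    d_naive <- mean_dist("naive_female", seed)
    d_cfa <- mean_dist("cfa", seed)
    d_nm <- mean_dist("naive_morphine", seed)
    d_cm <- mean_dist("cfa_morphine", seed)
    expect_lt(d_cfa, d_naive)     # inflammatory pain reduces locomotion
    expect_gt(d_nm, d_naive)      # morphine hyperlocomotion
    expect_gt(d_cm, d_nm)         # largest under CFA + morphine
  }
})
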