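test_that("simulation is deterministic and order-independent", {
  co1 <- simulate_cohort("naive_male", n_animals = 4, seed = 7)
  co2 <- simulate_cohort("naive_male", n_animals = 4, seed = 7)
  expect_identical(co1, co2)

  # distinct animals take distinct paths
  xs <- lapply(co1$tracks, function(t) t$samples$x_cm)
  expect_length(unique(xs), 4)

  # adding animals never changes an existing animal's path
  co3 <- simulate_cohort("naive_male", n_animals = 2, seed = 7)
  expect_identical(co3$tracks[[2]]$samples, co1$tracks[[2]]$samples)
})

test_that("zero locomotion pins the animal at its preferred position", {
  cfg <- simulation_config(t_pref_c = 31, sd_pref_c = 10, locomotion_scale = 0,
                           rest_hazard_per_s = 0, duration_s = 60,
                           start_mode = "preferred", seed = 1)
  tr <- simulate_track(cfg)
  expect_equal(unique(tr$samples$x_cm), 68.5)
  prof <- occupancy_profile(tr)
  expect_equal(max(prof$percent_by_zone), 100)
})

test_that("presets carry the condition parameterizations", {
  expect_equal(preset("naive_male")$config$t_pref_c, 30.4)
  expect_equal(preset("naive_female")$config$t_pref_c, 32.2)
  expect_equal(preset("naive_female")$config$sd_pref_c, 13.8)
  expect_equal(preset("cfa")$config$t_pref_c, 36.6)
  expect_equal(preset("cfa")$config$sd_pref_c, 6.1)
  expect_equal(preset("naive_morphine")$config$attraction_rate_per_s, 0)
  expect_error(preset("bogus"), "valid", class = "tgt_config_error")

  # preferred temperature outside the arena is a config error
  expect_error(simulate_track(simulation_config(t_pref_c = 70, seed = 1)),
               class = "tgt_config_error")
})

test_that("long-run temperature SD matches the configured preference width", {
  cfg <- simulation_config(t_pref_c = 31, sd_pref_c = 6, rest_hazard_per_s = 0,
                           duration_s = 7200, seed = 3)
  tr <- simulate_track(cfg)
  temps <- temperature_at_position(tr$samples$x_cm)
  expect_lt(abs(sd(temps) - 6) / 6, 0.10)
  expect_lt(abs(mean(temps) - 31), 1)
})

test_that("long-run position histogram is Gaussian about the preferred position", {
  # subsample every 25 s (~5 OU correlation times) so the chi-square
  # reference distribution applies; preference narrow enough that the
  # reflecting walls barely truncate
  arena <- arena_geometry()
  cal <- nominal_calibration()
  x_pref <- (31 - cal$intercept) / cal$slope
  sd_x <- 6 / cal$slope
  edges <- seq(0, arena$length_cm, length.out = arena$n_zones + 1)
  p <- diff(pnorm(edges, x_pref, sd_x))
  p <- p / sum(p)

  pass <- 0
  for (s in 1:10) {
    cfg <- simulation_config(t_pref_c = 31, sd_pref_c = 6,
                             rest_hazard_per_s = 0, duration_s = 7200,
                             seed = 200 + s)
    tr <- simulate_track(cfg)
    idx <- seq(1, nrow(tr$samples), by = 15 * 25)
    counts <- tabulate(zone_of_position(tr$samples$x_cm[idx], arena),
                       arena$n_zones)
    keep <- p * length(idx) >= 5
    counts2 <- c(sum(counts[!keep]), counts[keep])
    p2 <- c(sum(p[!keep]), p[keep])
    pv <- suppressWarnings(stats::chisq.test(counts2, p = p2)$p.value)
    if (pv > 0.01) pass <- pass + 1
  }
  expect_gte(pass, 9)
})

test_that("rest bouts are exponential with the configured mean", {
  cfg <- simulation_config(t_pref_c = 31, sd_pref_c = 6,
                           rest_hazard_per_s = 0.3, rest_mean_s = 4,
                           duration_s = 7200, seed = 5)
  tr <- simulate_track(cfg)
  # frozen frames identify bouts exactly: moving steps are continuous, so a
  # zero displacement only happens while resting
  r <- rle(diff(tr$samples$x_cm) == 0)
  durations <- r$lengths[r$values] / tr$fps
  expect_gt(length(durations), 500)
  expect_lt(abs(mean(durations) - 4) / 4, 0.10)
  # exponential shape: CV near 1
  expect_lt(abs(sd(durations) / mean(durations) - 1), 0.15)
})

test_that("locomotion rescaling leaves the stationary preference untouched", {
  sds <- sapply(c(0.7, 1, 1.5), function(scl) {
    cfg <- simulation_config(t_pref_c = 31, sd_pref_c = 6,
                             locomotion_scale = scl, rest_hazard_per_s = 0,
                             duration_s = 3600, seed = 17)
    sd(temperature_at_position(simulate_track(cfg)$samples$x_cm))
  })
  expect_true(all(abs(sds - 6) / 6 < 0.12))
})
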