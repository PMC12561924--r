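test_that("eccentricity is the angular offset of the eye from head-forward", {
  tb <- seq(0, 0.2, by = 1 / 90)
  te <- seq(0, 0.2, by = 1 / 250)
  mk <- function(lon, lat) {
    tr <- make_manual_trial(tb, head_yaw = rep(40, length(tb)),
                            head_pitch = rep(10, length(tb)),
                            torso_yaw = rep(0, length(tb)),
                            eye_lonlat = data.frame(lon = rep(lon, length(te)),
                                                    lat = rep(lat, length(te))),
                            t_eye = te)
    eccentricity_series(synchronize(tr))$ecc[1]
  }
  expect_equal(mk(0, 0), 0, tolerance = 1e-9)
  expect_equal(mk(10, 0), 10, tolerance = 1e-9)
  expect_equal(mk(30, 40), orthodromic(c(0, 0), c(30, 40)), tolerance = 1e-9)
})

test_that("eccentricity ignores global scene rotation", {
  tr <- generate_trial(default_profiles()$sit, default_cfg(), seed = 55)
  tr <- synchronize(tr)
  e1 <- eccentricity_series(tr)
  # rotate the world: premultiply every head quaternion by a fixed rotation
  q <- quat_from_yaw_pitch(111, -23)
  s <- tr$samples
  Q <- quat_multiply(q[rep(1, nrow(s)), ], cbind(s$qw, s$qx, s$qy, s$qz))
  tr$samples[, c("qw", "qx", "qy", "qz")] <- Q
  e2 <- eccentricity_series(tr)
  expect_equal(e1$ecc, e2$ecc)
})

test_that("saccade-locked averaging recovers a constructed V-shape minimum", {
  # deterministic eccentricity: V with minimum 17.8 deg at each saccade start
  t <- seq(0, 10, by = 0.004)
  starts <- seq(1, 9, by = 0.5)
  ecc <- rep(30, length(t))
  for (s in starts) {
    w <- abs(t - s) <= 0.45
    ecc[w] <- pmin(ecc[w], 17.8 + 40 * abs(t[w] - s))
  }
  sacc <- data.frame(t_start = starts)
  prof <- lock_to_saccade_starts(data.frame(t = t, ecc = ecc), sacc)
  expect_equal(prof$min_ecc, 17.8, tolerance = 1e-6)
  expect_equal(prof$n_events, length(starts))

  # single event: profile equals that event's segment exactly
  one <- lock_to_saccade_starts(data.frame(t = t, ecc = ecc),
                                data.frame(t_start = 5))
  seg <- approx(t, ecc, 5 + one$offset_ms / 1000)$y
  expect_equal(one$mean_ecc, seg, tolerance = 1e-9)
  expect_true(all(one$ci95 == 0))

  # events whose window leaves the trial are skipped and counted
  edge <- lock_to_saccade_starts(data.frame(t = t, ecc = ecc),
                                 data.frame(t_start = c(0.1, 5)))
  expect_equal(edge$n_skipped, 1L)
  expect_equal(edge$n_events, 1L)

  none <- lock_to_saccade_starts(data.frame(t = t, ecc = ecc),
                                 sacc[0, , drop = FALSE])
  expect_equal(none$n_events, 0L)
  expect_true(all(is.na(none$mean_ecc)))
})

test_that("rotation onsets are found at ramp starts and not in stillness", {
  t <- seq(0, 5, by = 1 / 250)
  yaw <- ifelse(t < 2, 0, pmin((t - 2) * 30, 45))
  on <- detect_rotation_onsets(t, yaw)
  expect_equal(length(on), 1L)
  expect_lt(abs(on - 2), 0.055)   # within the smoothing half-window

  expect_equal(length(detect_rotation_onsets(t, rep(12, length(t)))), 0L)

  # small jiggle below min_move never triggers
  set.seed(2)
  jig <- 1.5 * sin(2 * pi * t) * exp(-t)
  expect_equal(length(detect_rotation_onsets(t, jig)), 0L)
})

test_that("noisy ramp onsets localize within 20 ms on average", {
  # tracker error is slow drift, not white per-sample noise: an AR series
  # with 0.5 deg RMS and a multi-second correlation time
  t <- seq(0, 4, by = 1 / 250)
  rho <- exp(-diff(t)[1] / 4)
  errs <- c()
  set.seed(99)
  for (k in 1:20) {
    drift <- as.numeric(stats::filter(rnorm(length(t), 0, 0.5 * sqrt(1 - rho^2)),
                                      rho, method = "recursive"))
    yaw <- ifelse(t < 1.5, 0, pmin((t - 1.5) * 40, 50)) + drift
    on <- detect_rotation_onsets(t, yaw)
    on <- on[abs(on - 1.5) < 0.3]
    if (length(on)) errs <- c(errs, on[1] - 1.5)
  }
  expect_gt(length(errs), 15)
  expect_lt(abs(mean(errs)), 0.020)
})

test_that("head-torso pairing keeps matched onsets and drops orphans", {
  d <- head_torso_delay(head_onsets = 1.0, torso_onsets = 1.05)
  expect_equal(d$delays_ms, 50, tolerance = 1e-9)
  d2 <- head_torso_delay(head_onsets = 1.0, torso_onsets = 2.0)
  expect_true(d2$empty)
  d3 <- head_torso_delay(head_onsets = c(1.0, 3.0),
                         torso_onsets = c(1.06, 3.02, 5.0))
  expect_equal(d3$n_pairs, 2L)
  expect_equal(d3$delays_ms, c(60, 20), tolerance = 1e-9)
})

test_that("delay recovery over many generator trials is unbiased", {
  cfg <- default_cfg()
  pr <- default_profiles()$stand
  delays <- c()
  for (k in 1:120) {
    an <- analyze_trial(generate_trial(pr, cfg, seed = 20000 + k),
                        coverage = FALSE)
    delays <- c(delays, an$delay$delays_ms)
  }
  expect_gt(length(delays), 200)
  expect_lt(abs(mean(delays) - pr$head_torso_delay_ms), 5)
})

test_that("mean eccentricity declines before saccade onset and rises after", {
  cfg <- default_cfg()
  prof <- NULL
  for (k in 1:8) {
    an <- analyze_trial(generate_trial(default_profiles()$swivel, cfg,
                                       seed = 1300 + k), coverage = FALSE)
    prof <- if (is.null(prof)) an$ecc_profile
            else pool_ecc_profiles(list(prof, an$ecc_profile))
  }
  pre <- prof$mean_ecc[prof$offset_ms >= -300 & prof$offset_ms <= -50]
  expect_lt(mean(diff(pre)), 0)            # declining on average
  at0 <- prof$mean_ecc[prof$offset_ms == 0]
  at100 <- prof$mean_ecc[prof$offset_ms == 100]
  expect_gt(at100, at0 + 2)                # rapid post-saccadic rise
  expect_equal(prof$min_ecc, min(prof$mean_ecc[prof$offset_ms <= 0]))
})
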