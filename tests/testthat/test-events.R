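test_that("a stationary cluster yields exactly one fixation at its point", {
  g <- make_gaze_stream(25, -10, 0.2, trans_s = 0)
  fix <- detect_fixations(g)
  expect_equal(nrow(fix), 1L)
  expect_equal(fix$lon, 25, tolerance = 1e-9)
  expect_equal(fix$lat, -10, tolerance = 1e-9)
  expect_gte(fix$duration, 80)
  expect_equal(nrow(detect_fixations(g[0, ])), 0L)
})

test_that("two clusters separated by a brief transition yield two fixations", {
  g <- make_gaze_stream(c(0, 10), c(0, 0), c(0.2, 0.2), trans_s = 0.02)
  fix <- detect_fixations(g)
  expect_equal(nrow(fix), 2L)
  expect_lt(abs(fix$lon[1]), 1.5)
  expect_gt(fix$lon[2], 8.5)
  # agrees exactly with the brute-force windowing oracle
  win <- brute_idt(g)
  expect_equal(nrow(win), 2L)
  expect_equal(fix$t_start, g$t[win[, 1]])
  expect_equal(fix$t_end, g$t[win[, 2]])
})

test_that("continuous drift produces no fixations", {
  # 50 deg/s drift exceeds 3 deg dispersion within 60 ms < 80 ms
  t <- seq(0, 2, by = 1 / 250)
  g <- data.frame(t = t, lon = 50 * t, lat = 0)
  expect_equal(nrow(detect_fixations(g)), 0L)
})

test_that("detector matches the brute-force oracle on seeded random streams", {
  set.seed(1234)
  for (k in 1:50) {
    # random walk with dwell segments: a mix of fixation-like and moving
    n_seg <- sample(3:6, 1)
    lons <- cumsum(runif(n_seg, -15, 15))
    lats <- cumsum(runif(n_seg, -5, 5))
    durs <- runif(n_seg, 0.05, 0.25)
    g <- make_gaze_stream(lons, lats, durs, trans_s = runif(1, 0.01, 0.04))
    g$lon <- g$lon + rnorm(nrow(g), 0, 0.3)
    g$lat <- g$lat + rnorm(nrow(g), 0, 0.3)
    fix <- detect_fixations(g)
    win <- brute_idt(g)
    expect_equal(nrow(fix), if (is.null(win)) 0L else nrow(win))
    if (nrow(fix)) {
      expect_equal(fix$t_start, g$t[win[, 1]])
      expect_equal(fix$t_end, g$t[win[, 2]])
    }
  }
})

test_that("emitted fixations satisfy their invariants post hoc", {
  tr <- generate_trial(default_profiles()$stand, default_cfg(), seed = 31)
  g <- gaze_stream(synchronize(tr))
  fix <- detect_fixations(g)
  expect_gt(nrow(fix), 10)
  expect_true(all(verify_fixations(fix, g)))
  expect_true(all(diff(fix$t_start) > 0))
  expect_true(all(fix$t_end[-nrow(fix)] <= fix$t_start[-1]))
})

test_that("detection is invariant to time translation and scene rotation", {
  set.seed(8)
  g <- make_gaze_stream(c(0, 12, -5), c(3, -8, 20), c(0.15, 0.2, 0.12))
  g$lon <- g$lon + rnorm(nrow(g), 0, 0.2)
  fix0 <- detect_fixations(g)

  g_shift <- transform(g, t = t + 123.456)
  fix_s <- detect_fixations(g_shift)
  expect_equal(fix_s$t_start - 123.456, fix0$t_start, tolerance = 1e-9)
  expect_equal(fix_s$lon, fix0$lon)

  q <- quat_from_yaw_pitch(53, 17)
  vr <- quat_rotate(q[rep(1, nrow(g)), ], lonlat_to_vec(g))
  g_rot <- cbind(t = g$t, vec_to_lonlat(vr))
  fix_r <- detect_fixations(g_rot)
  expect_equal(fix_r$t_start, fix0$t_start)
  cr <- quat_rotate(q, lonlat_to_vec(fix0[, c("lon", "lat")]))
  expect_equal(as.matrix(lonlat_to_vec(fix_r[, c("lon", "lat")])),
               cr, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("saccades derive from adjacent fixation pairs", {
  fix <- data.frame(lon = c(0, 30), lat = c(0, 0),
                    t_start = c(0, 0.3), t_end = c(0.2, 0.5),
                    duration = c(200, 200))
  sac <- derive_saccades(fix)
  expect_equal(nrow(sac), 1L)
  expect_equal(sac$amplitude, 30, tolerance = 1e-9)
  expect_equal(sac$duration, 100)

  fix$t_start[2] <- 0.6    # 400 ms gap: ignored
  expect_equal(nrow(derive_saccades(fix)), 0L)
  expect_equal(nrow(derive_saccades(fix[1, ])), 0L)
})

test_that("a fixation chain's saccade amplitudes sum to the total distance", {
  set.seed(21)
  k <- 8
  fix <- data.frame(lon = runif(k, -60, 60), lat = runif(k, -30, 30),
                    t_start = (0:(k - 1)) * 0.25,
                    t_end = (0:(k - 1)) * 0.25 + 0.2,
                    duration = 200)
  sac <- derive_saccades(fix)
  expect_equal(nrow(sac), k - 1)
  manual <- sum(vapply(seq_len(k - 1), function(i)
    haversine_deg(fix$lon[i], fix$lat[i], fix$lon[i + 1], fix$lat[i + 1]),
    numeric(1)))
  expect_equal(total_distance(sac), manual, tolerance = 1e-9)
})

test_that("generator-default trials land in the basic-metrics bands", {
  cfg <- default_cfg()
  pr <- default_profiles()
  for (p in names(pr)) {
    nf <- c(); md <- c()
    for (k in 1:6) {
      an <- analyze_trial(generate_trial(pr[[p]], cfg, seed = 900 + k),
                          coverage = FALSE)
      nf <- c(nf, an$exploration$n_fixations)
      md <- c(md, an$exploration$mean_fix_dur)
    }
    expect_gte(mean(nf), 40)
    expect_lte(mean(nf), 55)
    expect_gte(mean(md), 150)
    expect_lte(mean(md), 250)
  }
})
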