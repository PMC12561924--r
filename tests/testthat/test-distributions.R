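test_that("frame points compute the nested relative frames with wrapping", {
  tb <- seq(0, 0.2, by = 1 / 90)
  n <- length(tb)
  tr <- make_manual_trial(tb, head_yaw = rep(70, n), head_pitch = rep(12, n),
                          torso_yaw = rep(50, n), chair_yaw = rep(20, n),
                          posture = "swivel")
  tr <- synchronize(tr)
  expect_equal(frame_points(tr, "head_rel_torso")$lon[1], 20, tolerance = 1e-6)
  expect_equal(frame_points(tr, "head_rel_torso")$lat[1], 12, tolerance = 1e-6)
  expect_equal(frame_points(tr, "torso_rel_chair")$lon[1], 30, tolerance = 1e-9)
  expect_equal(frame_points(tr, "torso_in_space")$lat[1], 0)
  expect_equal(frame_points(tr, "eyes_in_head")$lon[1], 0, tolerance = 1e-9)

  # wrap case: head 170, torso -170 -> head_rel_torso = -20
  tr2 <- make_manual_trial(tb, head_yaw = rep(170, n), head_pitch = rep(0, n),
                           torso_yaw = rep(-170, n))
  tr2 <- synchronize(tr2)
  expect_equal(frame_points(tr2, "head_rel_torso")$lon[1], -20,
               tolerance = 1e-6)
  # invariance to adding 360 to one operand
  expect_equal(wrap_lon((170 + 360) - (-170)), wrap_lon(170 - (-170)))

  tr3 <- make_manual_trial(tb, head_yaw = rep(0, n), head_pitch = rep(0, n),
                           torso_yaw = rep(0, n), posture = "sit")
  expect_error(frame_points(synchronize(tr3), "torso_rel_chair"),
               "swivel")
})

test_that("spread statistics aggregate subject-wise with sample SD", {
  pts <- data.frame(subject_id = rep(c("a", "b"), each = 4),
                    condition = "sit",
                    lon = c(5, 5, 5, 5, -10, 10, -10, 10),
                    lat = c(1, 1, 1, 1, 0, 0, 0, 0))
  ss <- spread_stats(pts)
  expect_equal(ss$cells$sd_lon[ss$cells$subject_id == "a"], 0)
  expect_equal(ss$cells$sd_lon[ss$cells$subject_id == "b"],
               sd(c(-10, 10, -10, 10)))  # ddof = 1
  expect_equal(ss$condition$sd_lon, mean(c(0, sd(c(-10, 10, -10, 10)))))
  # two points {-10, 10}: sample SD = 14.14
  expect_equal(sd(c(-10, 10)), 14.1421356, tolerance = 1e-6)
  expect_warning(spread_stats(data.frame(subject_id = "a", condition = "x",
                                         lon = 1, lat = 1)), "missing")
})

test_that("equator bias matches the hand-computed t and d on a toy table", {
  lat <- c(15.2, 16.4, 15.8, 16.1, 16.0)
  res <- equator_bias(data.frame(subject_id = letters[1:5], mean_lat = lat))
  m <- mean(lat); s <- sd(lat)
  expect_equal(res$t, m / (s / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$d, m / s, tolerance = 1e-12)
  expect_equal(res$d, res$t / sqrt(5), tolerance = 1e-12)
  expect_gt(res$t, 50)
  zero <- equator_bias(data.frame(mean_lat = rep(0, 4)))
  expect_true(zero$zero_variance)
  expect_equal(zero$bias, 0)
})

test_that("head-direction split assigns eyes-in-head points by velocity sign", {
  tb <- seq(0, 2, by = 1 / 90)
  n <- length(tb)
  # head rotating rightward at 20 deg/s, eyes locked 15 deg right of head
  te <- seq(0, 2, by = 1 / 250)
  tr <- make_manual_trial(tb, head_yaw = 20 * tb, head_pitch = rep(0, n),
                          torso_yaw = rep(0, n),
                          eye_lonlat = data.frame(lon = rep(15, length(te)),
                                                  lat = rep(0, length(te))),
                          t_eye = te)
  sp <- split_by_head_direction(synchronize(tr))
  expect_equal(nrow(sp$leftward), 0L)
  expect_gt(nrow(sp$rightward), 400)
  expect_equal(mean(sp$rightward$lon), 15, tolerance = 0.1)

  trs <- make_manual_trial(tb, head_yaw = rep(30, n), head_pitch = rep(0, n),
                           torso_yaw = rep(0, n))
  sps <- split_by_head_direction(synchronize(trs))
  expect_equal(nrow(sps$rightward), 0L)
  expect_equal(nrow(sps$leftward), 0L)
})

test_that("bimodality detection finds symmetric side peaks and not noise", {
  set.seed(4)
  x <- c(rnorm(3000, -12, 3), rnorm(3000, 12, 3))
  b <- detect_bimodality(x)
  expect_true(b$bimodal)
  expect_lt(abs(b$peak_left + 12), 2)
  expect_lt(abs(b$peak_right - 12), 2)

  u <- detect_bimodality(rnorm(5000, 0, 10))
  expect_false(u$bimodal)
  expect_error(detect_bimodality(rnorm(50)), "100")

  # binned input gives the same answer
  h <- hist(x, breaks = seq(-60, 60, by = 1), plot = FALSE)
  bb <- detect_bimodality(h$mids, weights = h$counts)
  expect_true(bb$bimodal)
  expect_lt(abs(bb$peak_right - 12), 2.5)
})

test_that("heatmaps bin, normalize, and respect spherical area weighting", {
  pts <- data.frame(lon = rep(10.2, 50), lat = rep(-3.4, 50))
  hm <- gaze_heatmap(pts, 360, 180, smoothing = 0)
  expect_equal(sum(hm), 1)
  expect_equal(max(hm), 1)   # all mass in one bin
  hm_s <- gaze_heatmap(pts, 360, 180, smoothing = 2)
  expect_equal(sum(hm_s), 1, tolerance = 1e-9)
  expect_lt(max(hm_s), 1)

  set.seed(31)
  z <- runif(1e5, -1, 1); phi <- runif(1e5, -180, 180)
  uni <- data.frame(lon = phi, lat = asin(z) * 180 / pi)
  hmu <- gaze_heatmap(uni, 36, 18)
  band <- rowSums(hmu)
  lat_mid <- seq(-85, 85, by = 10)
  expected <- (sin((lat_mid + 5) * pi / 180) - sin((lat_mid - 5) * pi / 180)) / 2
  expect_lt(max(abs(band - expected)), 0.004)
})
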