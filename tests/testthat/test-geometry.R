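test_that("lon/lat and unit-vector representations round-trip", {
  expect_equal(unname(lonlat_to_vec(c(0, 0))[1, ]), c(1, 0, 0))
  expect_equal(unname(lonlat_to_vec(c(0, 90))[1, ]), c(0, 0, 1))
  expect_equal(unname(lonlat_to_vec(c(90, 0))[1, ]), c(0, 1, 0))
  expect_equal(vec_to_lonlat(c(1, 0, 0)), data.frame(lon = 0, lat = 0))
  expect_equal(vec_to_lonlat(c(0, 0, 1)), data.frame(lon = 0, lat = 90))

  p <- vec_to_lonlat(lonlat_to_vec(c(37, -12)))
  expect_equal(p$lon, 37, tolerance = 1e-9)
  expect_equal(p$lat, -12, tolerance = 1e-9)

  set.seed(42)
  v <- matrix(rnorm(3000), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  rt <- lonlat_to_vec(vec_to_lonlat(v))
  expect_lt(max(abs(rt - v)), 1e-9 * pi / 180 + 1e-12)

  expect_error(vec_to_lonlat(c(0, 0, 0)), "zero")
})

test_that("longitude wraps and poles canonicalize", {
  expect_equal(wrap_lon(c(-180, 180, 540, -540.5)), c(-180, -180, 180 - 360, 179.5))
  expect_equal(sphere_point(123, 0)$lon, sphere_point(123 + 360, 0)$lon)
  expect_equal(sphere_point(45, 90)$lon, 0)
  expect_equal(sphere_point(-77, -90)$lon, 0)
  expect_error(sphere_point(0, 91), "latitude")
})

test_that("orthodromic distance matches the haversine oracle", {
  expect_equal(orthodromic(c(0, 0), c(0, 0)), 0)
  expect_equal(orthodromic(c(0, 0), c(90, 0)), 90)
  expect_equal(orthodromic(c(12, 34), c(-56, 7)),
               haversine_deg(12, 34, -56, 7), tolerance = 1e-9)
  set.seed(7)
  for (k in 1:200) {
    a <- c(runif(1, -180, 180), runif(1, -90, 90))
    b <- c(runif(1, -180, 180), runif(1, -90, 90))
    expect_equal(orthodromic(a, b), haversine_deg(a[1], a[2], b[1], b[2]),
                 tolerance = 1e-9)
  }
})

test_that("orthodromic is a metric on random triples", {
  set.seed(11)
  for (k in 1:200) {
    p <- data.frame(lon = runif(3, -180, 180), lat = runif(3, -90, 90))
    d12 <- orthodromic(p[1, ], p[2, ])
    d21 <- orthodromic(p[2, ], p[1, ])
    d13 <- orthodromic(p[1, ], p[3, ])
    d23 <- orthodromic(p[2, ], p[3, ])
    expect_equal(d12, d21, tolerance = 1e-12)
    expect_gte(d13 + d23 + 1e-9, d12)
    expect_gte(d12, 0)
  }
  expect_lt(orthodromic(c(5, 5), c(5, 5)), 1e-12)
})

test_that("gaze integration composes eye and head rotations correctly", {
  eye_fwd <- c(1, 0, 0)
  q_id <- c(1, 0, 0, 0)
  expect_equal(integrate_gaze(eye_fwd, q_id), data.frame(lon = 0, lat = 0))

  q_yaw90 <- quat_from_yaw_pitch(90, 0)
  g <- integrate_gaze(eye_fwd, q_yaw90)
  expect_equal(g$lon, 90, tolerance = 1e-9)
  expect_equal(g$lat, 0, tolerance = 1e-9)

  # eye at (10, 0) in head + 30 deg yaw -> (40, 0), checked against an
  # explicit rotation-matrix composition
  eye_v <- lonlat_to_vec(c(10, 0))
  q30 <- quat_from_yaw_pitch(30, 0)
  g <- integrate_gaze(eye_v, q30)
  Rm <- rotmat_from_quat(q30[1, ])
  expect_equal(unname(as.matrix(lonlat_to_vec(g))[1, ]),
               unname(as.numeric(Rm %*% eye_v[1, ])), tolerance = 1e-9)
  expect_equal(g$lon, 40, tolerance = 1e-9)

  expect_error(integrate_gaze(eye_fwd, c(2, 0, 0, 0)), "norm")
})

test_that("quaternion rotation agrees with rotation matrices; q and -q match", {
  set.seed(3)
  for (k in 1:100) {
    q <- random_quat()
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    expect_equal(as.numeric(quat_rotate(q, v)),
                 as.numeric(rotmat_from_quat(q) %*% v), tolerance = 1e-12)
    g1 <- integrate_gaze(matrix(v, 1), matrix(q, 1))
    g2 <- integrate_gaze(matrix(v, 1), matrix(-q, 1))
    expect_identical(g1, g2)
  }
  # Hamilton product consistency: rotating by q1*q2 = rotating by q2 then q1
  q1 <- random_quat(); q2 <- random_quat()
  v <- c(0.6, -0.64, 0.48)
  expect_equal(as.numeric(quat_rotate(quat_multiply(q1, q2), v)),
               as.numeric(quat_rotate(q1, quat_rotate(q2, v))),
               tolerance = 1e-12)
})

test_that("slerp follows the geodesic", {
  set.seed(9)
  for (k in 1:20) {
    q1 <- random_quat(); q2 <- random_quat()
    mid <- quat_slerp(q1, q2, 0.5)[1, ]
    # geodesic midpoint oracle: normalize(q1 + sgn * q2)
    sgn <- if (sum(q1 * q2) < 0) -1 else 1
    m2 <- q1 + sgn * q2
    m2 <- m2 / sqrt(sum(m2^2))
    expect_lt(min(sqrt(sum((mid - m2)^2)), sqrt(sum((mid + m2)^2))), 1e-9)
  }
  expect_equal(quat_slerp(c(1, 0, 0, 0), c(1, 0, 0, 0), 0.3)[1, 1], 1)
})

test_that("cap fraction reproduces the analytic cap area", {
  expect_equal(round(cap_fraction(3), 5), 0.06852)
  expect_equal(cap_fraction(90), 50)
  expect_equal(cap_fraction(180), 100)
  th <- seq(0.5, 179.5, by = 0.5)
  expect_true(all(diff(cap_fraction(th)) > 0))
  expect_error(cap_fraction(-1), "theta")
  expect_error(cap_fraction(181), "theta")

  # Monte-Carlo cap area at a random radius, 1e6 uniform sphere points
  set.seed(5)
  theta <- 37
  z <- runif(1e6, -1, 1)
  p_hat <- mean(z >= cos(theta * pi / 180))
  se <- sqrt(p_hat * (1 - p_hat) / 1e6)
  expect_lt(abs(cap_fraction(theta) / 100 - p_hat), 3 * se)
})

test_that("equirectangular binning wraps at the +/-180 meridian", {
  b <- equirect_bin(c(0, 0), 360, 180)
  expect_equal(b$i_lon, 181L)   # first bin of the eastern half
  expect_equal(b$i_lat, 91L)
  bw <- equirect_bin(data.frame(lon = c(-180, 179.999), lat = c(0, 0)), 360, 180)
  expect_equal(bw$i_lon, c(1L, 360L))   # adjacent under wraparound
  expect_equal(equirect_bin(c(-180 + 1e-9, 0), 360, 180)$i_lon, 1L)

  # uniform sphere points: per-band counts proportional to cos(lat)
  set.seed(13)
  z <- runif(2e5, -1, 1); phi <- runif(2e5, -180, 180)
  pts <- data.frame(lon = phi, lat = asin(z) * 180 / pi)
  bb <- equirect_bin(pts, 36, 18)
  counts <- tabulate(bb$i_lat, 18)
  lat_mid <- seq(-85, 85, by = 10)
  expected <- 2e5 * (sin((lat_mid + 5) * pi / 180) - sin((lat_mid - 5) * pi / 180)) / 2
  expect_lt(max(abs(counts - expected) / sqrt(expected)), 5)
})

test_that("fibonacci lattice is unit-norm and near equal-area", {
  G <- fibonacci_grid(20000)
  expect_lt(max(abs(sqrt(rowSums(G^2)) - 1)), 1e-12)
  # band occupancy proportional to band area
  lat <- asin(G[, 3]) * 180 / pi
  counts <- tabulate(findInterval(lat, seq(-90, 90, by = 15),
                                  rightmost.closed = TRUE), 12)
  edges <- seq(-90, 90, by = 15) * pi / 180
  frac <- diff(sin(edges)) / 2
  expect_lt(max(abs(counts / 20000 - frac) / frac), 0.01)
})
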