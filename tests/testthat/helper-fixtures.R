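# Shared fixtures, all built in code.

# a gaze stream dwelling at given points for given durations (s), with
# linear transitions between them
make_gaze_stream <- function(lons, lats, durs, trans_s = 0.02, rate = 250) {
  dt <- 1 / rate
  t <- c(); lon <- c(); lat <- c()
  tcur <- 0
  for (k in seq_along(lons)) {
    if (k > 1 && trans_s > 0) {
      tt <- seq(tcur + dt, tcur + trans_s, by = dt)
      f <- (tt - tcur) / trans_s
      t <- c(t, tt)
      lon <- c(lon, lons[k - 1] * (1 - f) + lons[k] * f)
      lat <- c(lat, lats[k - 1] * (1 - f) + lats[k] * f)
      tcur <- tcur + trans_s
    }
    tt <- seq(tcur + dt, tcur + durs[k], by = dt)
    t <- c(t, tt)
    lon <- c(lon, rep(lons[k], length(tt)))
    lat <- c(lat, rep(lats[k], length(tt)))
    tcur <- tcur + durs[k]
  }
  data.frame(t = t - t[1], lon = lon, lat = lat)
}

# a minimal hand-built trial with prescribed head yaw/pitch and torso yaw
# series; eye vectors point at given gaze targets in head coordinates
make_manual_trial <- function(t_body, head_yaw, head_pitch, torso_yaw,
                              chair_yaw = 0, posture = "stand",
                              eye_lonlat = NULL, t_eye = NULL) {
  q <- quat_from_yaw_pitch(head_yaw, head_pitch)
  body <- data.frame(t = t_body, qw = q[, 1], qx = q[, 2], qy = q[, 3],
                     qz = q[, 4], torso_yaw = torso_yaw,
                     chair_yaw = chair_yaw)
  if (is.null(t_eye)) t_eye <- seq(min(t_body), max(t_body), by = 1 / 250)
  if (is.null(eye_lonlat))
    eye_lonlat <- data.frame(lon = rep(0, length(t_eye)),
                             lat = rep(0, length(t_eye)))
  v <- lonlat_to_vec(eye_lonlat)
  eye <- data.frame(t = t_eye, ex = v[, 1], ey = v[, 2], ez = v[, 3])
  vr_trial("t01", posture, "indoor", eye, body)
}

# generator shorthand used by several files
default_cfg <- function(...) generator_config(seed = 1, ...)

quiet_profile <- function() {
  posture_profile("stand", gaze_lon_sd = 0, gaze_lat_sd = 0,
                  torso_lon_sd = 0, torso_rel_chair_sd = NA,
                  head_lat_bias = 0, eye_in_head_lat_bias = 0,
                  ecc_min = 0, head_torso_delay_ms = 0)
}
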