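# Longitude/latitude distributions of every effector frame, their spreads
# and biases, and the conditional eyes-in-head analyses.

FRAMES <- c("eyes_in_space", "head_in_space", "torso_in_space",
            "torso_rel_chair", "head_rel_torso", "eyes_in_head")

#' Per-sample points of an effector reference frame
#'
#' Computes, from a synchronized trial, the lon/lat point time series of the
#' requested frame of the nested effector hierarchy:
#' \describe{
#'   \item{eyes_in_space}{eye-in-head vector rotated by the head quaternion
#'     (gaze).}
#'   \item{head_in_space}{head-forward axis intersected with the sphere.}
#'   \item{torso_in_space}{torso yaw; latitude structurally 0.}
#'   \item{torso_rel_chair}{torso yaw minus chair yaw (swivel trials only).}
#'   \item{head_rel_torso}{head longitude minus torso yaw; latitude from
#'     head pitch.}
#'   \item{eyes_in_head}{the raw eye-in-head direction.}
#' }
#' All angular differences are wrapped to `[-180, 180)`, so adding 360 to
#' either operand changes nothing.
#'
#' @param trial a synchronized `vr_trial`.
#' @param frame one of the six frame names above.
#' @return data.frame `t`, `lon`, `lat` with attribute `"frame"`.
#' @export
frame_points <- function(trial, frame = FRAMES) {
  frame <- match.arg(frame)
  s <- need_samples(trial)
  fwd <- c(1, 0, 0)
  out <- switch(frame,
    eyes_in_space = gaze_stream(trial)[, c("lon", "lat")],
    head_in_space = vec_to_lonlat(quat_rotate(cbind(s$qw, s$qx, s$qy, s$qz),
                                              matrix(fwd, 1))),
    torso_in_space = data.frame(lon = wrap_lon(s$torso_yaw), lat = 0),
    torso_rel_chair = {
      if (trial$posture != "swivel")
        stop("frame_points: torso_rel_chair is only defined for swivel trials")
      data.frame(lon = wrap_lon(s$torso_yaw - s$chair_yaw), lat = 0)
    },
    head_rel_torso = {
      h <- vec_to_lonlat(quat_rotate(cbind(s$qw, s$qx, s$qy, s$qz),
                                     matrix(fwd, 1)))
      data.frame(lon = wrap_lon(h$lon - s$torso_yaw), lat = h$lat)
    },
    eyes_in_head = vec_to_lonlat(cbind(s$ex, s$ey, s$ez)))
  out <- data.frame(t = s$t, lon = out$lon, lat = out$lat)
  attr(out, "frame") <- frame
  out
}

#' Longitude/latitude spread per subject and condition
#'
#' Linear (non-circular) standard deviations of longitude and latitude,
#' computed per subject x condition cell after pooling that subject's
#' trials, then averaged over subjects to give the condition value. The
#' linear SD is well defined here because trials start centred at (0, 0)
#' and observed spreads stay far from wrap saturation; it would be
#' misleading for near-uniform circular data. Sample SD (ddof = 1) is used
#' at the subject level throughout.
#'
#' @param points data.frame with columns `subject_id`, `condition`, `lon`,
#'   `lat` (one row per point, trials already pooled or stacked).
#' @return list with `cells` (per subject x condition `sd_lon`, `sd_lat`,
#'   `mean_lat`, `n`) and `condition` (mean over subjects per condition).
#' @export
spread_stats <- function(points) {
  stopifnot(all(c("subject_id", "condition", "lon", "lat") %in% names(points)))
  key <- interaction(points$subject_id, points$condition, drop = TRUE)
  ns <- tapply(points$lon, key, length)
  if (any(ns < 2)) {
    bad <- names(ns)[ns < 2]
    warning("spread_stats: cells with < 2 points flagged missing: ",
            paste(bad, collapse = ", "))
  }
  cells <- do.call(rbind, lapply(split(points, key), function(d) {
    data.frame(subject_id = d$subject_id[1], condition = d$condition[1],
               sd_lon = if (nrow(d) >= 2) stats::sd(d$lon) else NA_real_,
               sd_lat = if (nrow(d) >= 2) stats::sd(d$lat) else NA_real_,
               mean_lat = mean(d$lat), n = nrow(d))
  }))
  rownames(cells) <- NULL
  cond <- stats::aggregate(cells[c("sd_lon", "sd_lat", "mean_lat")],
                           by = list(condition = cells$condition),
                           FUN = mean, na.rm = TRUE)
  list(cells = cells, condition = cond)
}

# spreads from accumulated first/second moments (used by run_study, which
# never materialises the full sample-level point sets)
spread_from_moments <- function(m) {
  sd1 <- function(n, s, s2) sqrt(pmax((s2 - s^2 / n) / (n - 1), 0))
  cells <- data.frame(subject_id = m$subject_id, condition = m$condition,
                      sd_lon = sd1(m$n, m$sum_lon, m$sum_lon2),
                      sd_lat = sd1(m$n, m$sum_lat, m$sum_lat2),
                      mean_lat = m$sum_lat / m$n, n = m$n)
  cond <- stats::aggregate(cells[c("sd_lon", "sd_lat", "mean_lat")],
                           by = list(condition = cells$condition),
                           FUN = mean, na.rm = TRUE)
  list(cells = cells, condition = cond)
}

#' Equator bias of a frame's latitude distribution
#'
#' Subject-wise mean latitudes tested against the equator with a one-sample
#' t-test plus Cohen's d (see [one_sample_bias_test()]).
#'
#' @param subject_means data.frame with `subject_id` and `mean_lat` (one row
#'   per subject), e.g. the `cells` table of [spread_stats()] for one
#'   condition.
#' @return list: `bias` (grand mean latitude), `t`, `df`, `p`, `d`,
#'   `zero_variance` flag.
#' @export
equator_bias <- function(subject_means) {
  stopifnot("mean_lat" %in% names(subject_means))
  one_sample_bias_test(subject_means$mean_lat)
}

#' Split eyes-in-head points by horizontal head movement direction
#'
#' The eyes lead the head: while the head rotates rightward the eye rests
#' right of the head's forward axis, and conversely leftward. This splits
#' the eyes-in-head samples by the sign of the smoothed head yaw angular
#' velocity; samples with |velocity| inside the dead band count as "head not
#' moving" and belong to neither set.
#'
#' @param trial a synchronized `vr_trial`.
#' @param dead_band_deg_s velocity dead band (default 5 deg/s).
#' @param smooth_ms boxcar smoothing window for the velocity (default 100).
#' @return list of two data.frames, `rightward` and `leftward`, each with
#'   `t`, `lon`, `lat` of the eyes-in-head points.
#' @export
split_by_head_direction <- function(trial, dead_band_deg_s = 5,
                                    smooth_ms = 100) {
  s <- need_samples(trial)
  head_lon <- frame_points(trial, "head_in_space")$lon
  v <- yaw_velocity(s$t, head_lon, smooth_ms)
  eih <- frame_points(trial, "eyes_in_head")
  list(rightward = eih[!is.na(v) & v > dead_band_deg_s, ],
       leftward = eih[!is.na(v) & v < -dead_band_deg_s, ])
}

# smoothed angular velocity (deg/s) of a wrapped yaw series
yaw_velocity <- function(t, yaw, smooth_ms = 100) {
  y <- unwrap_deg(yaw)
  dt <- median(diff(t))
  v <- c(NA, diff(y) / diff(t))
  k <- max(1L, round(smooth_ms / 1000 / dt))
  if (k > 1) {
    v <- stats::filter(v, rep(1 / k, k), sides = 2)
    v <- as.numeric(v)
  }
  v
}

#' Detect left/right bimodality of a longitude distribution
#'
#' Kernel-density estimate of the longitudes; the highest local maximum on
#' each side of the meridian (beyond a small separation zone) is a side-peak
#' candidate. The distribution is flagged bimodal when both candidates exist
#' and each reaches at least `prominence` of the global density maximum, so
#' a unimodal centre-peaked distribution with noise ripples in its tails is
#' not flagged.
#'
#' @param lons numeric vector of longitudes in degrees (>= 100 points), or a
#'   binned representation via `weights`.
#' @param weights optional nonnegative weights (e.g. bin counts for binned
#'   longitudes).
#' @param prominence minimum side-peak height as a fraction of the global
#'   density maximum (default 0.2).
#' @param min_sep half-width of the central exclusion zone in degrees
#'   (default 5): a side peak must sit beyond it.
#' @return list: `bimodal` flag, `peak_left`, `peak_right` (degrees; NA when
#'   absent).
#' @export
detect_bimodality <- function(lons, weights = NULL, prominence = 0.2,
                              min_sep = 5) {
  if (is.null(weights) && length(lons) < 100)
    stop("detect_bimodality: need at least 100 points")
  if (is.null(weights)) {
    den <- stats::density(lons, bw = "nrd0")
  } else {
    w <- weights / sum(weights)
    keep <- w > 0
    den <- stats::density(lons[keep], weights = w[keep],
                          bw = stats::bw.nrd0(rep(lons[keep],
                                                  pmax(1, round(w[keep] * 1e4)))))
  }
  y <- den$y; x <- den$x
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- data.frame(x = x[is_max], h = y[is_max])
  gmax <- max(y)
  side <- function(sgn) {
    cand <- peaks[sgn * peaks$x > min_sep, ]
    if (nrow(cand) == 0) return(c(NA_real_, NA_real_))
    k <- which.max(cand$h)
    c(cand$x[k], cand$h[k])
  }
  r <- side(1); l <- side(-1)
  bimodal <- !is.na(r[1]) && !is.na(l[1]) &&
    r[2] >= prominence * gmax && l[2] >= prominence * gmax
  list(bimodal = bimodal,
       peak_left = if (bimodal) l[1] else NA_real_,
       peak_right = if (bimodal) r[1] else NA_real_)
}

#' Equirectangular density grid of a point set
#'
#' Bins points on the lon x lat map, optionally smooths with a separable
#' Gaussian (wrapping across the +/-180 meridian, reflecting at the poles),
#' and normalizes the grid to sum to 1. Note the map is area-distorted near
#' the poles: uniform points on the sphere produce per-band mass
#' proportional to cos(latitude), not a flat grid.
#'
#' @param points data.frame with `lon`, `lat`.
#' @param n_lon,n_lat grid size (default 360 x 180).
#' @param smoothing Gaussian sigma in degrees (0 = none).
#' @return `n_lat` x `n_lon` matrix summing to 1 (row 1 = south edge).
#' @export
gaze_heatmap <- function(points, n_lon = 360, n_lat = 180, smoothing = 0) {
  b <- equirect_bin(points, n_lon, n_lat)
  grid <- matrix(0, n_lat, n_lon)
  tab <- table(factor(b$i_lat, levels = 1:n_lat),
               factor(b$i_lon, levels = 1:n_lon))
  grid <- grid + unclass(tab)
  if (smoothing > 0) {
    sg_lon <- smoothing / (360 / n_lon)
    sg_lat <- smoothing / (180 / n_lat)
    grid <- smooth_rows_wrap(t(smooth_rows_reflect(grid, sg_lat)), sg_lon)
    grid <- t(grid)
  }
  total <- sum(grid)
  if (total > 0) grid <- grid / total
  grid
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

smooth_rows_wrap <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  t(apply(m, 1, function(row) {
    ext <- c(utils::tail(row, r), row, utils::head(row, r))
    as.numeric(stats::filter(ext, k, sides = 2))[(r + 1):(r + length(row))]
  }))
}

smooth_rows_reflect <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  apply(m, 2, function(col) {
    ext <- c(rev(utils::head(col, r)), col, rev(utils::tail(col, r)))
    as.numeric(stats::filter(ext, k, sides = 2))[(r + 1):(r + length(col))]
  })
}
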