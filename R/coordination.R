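# Temporal coordination of the effectors: eyes-in-head eccentricity locked
# to saccade onsets, and head-to-torso rotation-onset delays.

#' Eyes-in-head eccentricity time series
#'
#' Angular deviation of the eye direction from the head's forward axis,
#' i.e. the orthodromic distance of the eyes-in-head point from (0, 0).
#' Depends only on the eye-in-head vector, so it is invariant to any global
#' rotation of the scene.
#'
#' @param trial a synchronized `vr_trial`.
#' @return data.frame `t`, `ecc` (degrees).
#' @export
eccentricity_series <- function(trial) {
  s <- need_samples(trial)
  E <- cbind(s$ex, s$ey, s$ez)
  E <- E / sqrt(rowSums(E^2))
  data.frame(t = s$t, ecc = acos(pmin(pmax(E[, 1], -1), 1)) * 180 / pi)
}

#' Average eccentricity profile time-locked to saccade starts
#'
#' For each saccade start, the eccentricity segment in
#' `[window_ms[1], window_ms[2]]` around it is extracted on a fixed bin
#' grid; segments are averaged across events per bin, with a 95% confidence
#' interval from the between-event standard error. The reported minimum is
#' the minimum of the event-averaged curve at or before offset 0 (the head
#' aligns with the eyes during the preceding fixation, so eccentricity
#' bottoms out just as the next saccade launches). Events whose window
#' exceeds the trial bounds are skipped and counted.
#'
#' @param ecc data.frame `t`, `ecc` from [eccentricity_series()].
#' @param saccades saccade table of the same trial.
#' @param window_ms two-element window relative to saccade start, default
#'   `c(-400, 200)`.
#' @param bin_ms bin width in ms (default 4, matching a 250 Hz timebase).
#' @return object of class `ecc_profile`: list with `offset_ms`, `mean_ecc`,
#'   `ci95`, `min_ecc`, `n_events`, `n_skipped`, plus per-bin accumulators
#'   (`n`, `sum`, `sum2`) so profiles pool across trials.
#' @export
lock_to_saccade_starts <- function(ecc, saccades, window_ms = c(-400, 200),
                                   bin_ms = 4) {
  offsets <- seq(window_ms[1], window_ms[2], by = bin_ms)
  nb <- length(offsets)
  acc <- list(offset_ms = offsets, n = integer(nb), sum = numeric(nb),
              sum2 = numeric(nb), n_events = 0L, n_skipped = 0L)
  class(acc) <- "ecc_profile"
  if (nrow(saccades) == 0) return(finalize_ecc_profile(acc))
  t0 <- ecc$t[1]; t1 <- ecc$t[nrow(ecc)]
  for (st in saccades$t_start) {
    tq <- st + offsets / 1000
    if (tq[1] < t0 - 1e-9 || tq[nb] > t1 + 1e-9) {
      acc$n_skipped <- acc$n_skipped + 1L
      next
    }
    seg <- stats::approx(ecc$t, ecc$ecc, tq, rule = 2)$y
    acc$n <- acc$n + 1L
    acc$sum <- acc$sum + seg
    acc$sum2 <- acc$sum2 + seg^2
    acc$n_events <- acc$n_events + 1L
  }
  finalize_ecc_profile(acc)
}

#' Pool eccentricity profiles across trials
#'
#' Event-level pooling of the per-bin accumulators, so the condition-level
#' profile weights every saccade event equally regardless of trial.
#'
#' @param profiles list of `ecc_profile` objects on identical bin grids.
#' @return pooled `ecc_profile`.
#' @export
pool_ecc_profiles <- function(profiles) {
  stopifnot(length(profiles) > 0)
  acc <- profiles[[1]]
  for (p in profiles[-1]) {
    stopifnot(identical(p$offset_ms, acc$offset_ms))
    acc$n <- acc$n + p$n
    acc$sum <- acc$sum + p$sum
    acc$sum2 <- acc$sum2 + p$sum2
    acc$n_events <- acc$n_events + p$n_events
    acc$n_skipped <- acc$n_skipped + p$n_skipped
  }
  finalize_ecc_profile(acc)
}

finalize_ecc_profile <- function(acc) {
  n <- acc$n
  acc$mean_ecc <- ifelse(n > 0, acc$sum / n, NA_real_)
  vr <- ifelse(n > 1, (acc$sum2 - acc$sum^2 / pmax(n, 1)) / pmax(n - 1, 1), 0)
  acc$ci95 <- 1.96 * sqrt(pmax(vr, 0) / pmax(n, 1))
  pre <- acc$offset_ms <= 0
  acc$min_ecc <- if (any(n[pre] > 0)) min(acc$mean_ecc[pre], na.rm = TRUE) else NA_real_
  acc
}

#' @export
print.ecc_profile <- function(x, ...) {
  cat(sprintf("<ecc_profile> %d events (%d skipped), window [%g, %g] ms\n",
              x$n_events, x$n_skipped, min(x$offset_ms), max(x$offset_ms)))
  if (is.finite(x$min_ecc))
    cat(sprintf("  minimum of mean curve at/before saccade start: %.2f deg\n",
                x$min_ecc))
  invisible(x)
}

#' Detect rotation onsets in a yaw time series
#'
#' An onset is the moment the smoothed angular speed crosses `vel_thresh`
#' upward, provided the ensuing movement accumulates at least
#' `min_move_deg` of path before the speed falls back below the hysteresis
#' level. The hysteresis (re-arm only after the speed drops below
#' `hyst_thresh`) prevents double triggering within one movement bout.
#'
#' @param t,yaw time (s) and yaw (degrees) series.
#' @param vel_thresh onset speed threshold (default 10 deg/s).
#' @param hyst_thresh re-arm speed (default 5 deg/s).
#' @param min_move_deg minimum accumulated movement (default 5).
#' @param smooth_ms boxcar smoothing of the speed (default 50).
#' @return numeric vector of onset times (seconds).
#' @export
detect_rotation_onsets <- function(t, yaw, vel_thresh = 10, hyst_thresh = 5,
                                   min_move_deg = 5, smooth_ms = 50) {
  v <- yaw_velocity(t, yaw, smooth_ms)
  sp <- abs(v)
  sp[is.na(sp)] <- 0
  y <- unwrap_deg(yaw)
  n <- length(sp)
  onsets <- numeric(0)
  armed <- TRUE
  i <- 2L
  while (i <= n) {
    if (armed && sp[i] >= vel_thresh && sp[i - 1] < vel_thresh) {
      j <- i
      while (j < n && sp[j] >= hyst_thresh) j <- j + 1L
      moved <- sum(abs(diff(y[i:j])))
      if (moved >= min_move_deg) onsets <- c(onsets, t[i])
      armed <- FALSE
      i <- j
    } else {
      if (sp[i] < hyst_thresh) armed <- TRUE
      i <- i + 1L
    }
  }
  onsets
}

#' Head-to-torso rotation onset delays
#'
#' Pairs each torso rotation onset with the nearest preceding-or-concurrent
#' head onset within `max_pair_gap_ms`; unpaired onsets on either side are
#' dropped. Delays are signed (torso minus head), so a positive mean says
#' the torso follows the head.
#'
#' @param head_onsets,torso_onsets time-ordered onset times (seconds).
#' @param max_pair_gap_ms largest head-to-torso gap considered one
#'   reorientation (default 500).
#' @return list: `delays_ms` (per matched pair), `mean_delay_ms`, `n_pairs`,
#'   `empty` flag.
#' @export
head_torso_delay <- function(head_onsets, torso_onsets, max_pair_gap_ms = 500) {
  delays <- numeric(0)
  for (to in torso_onsets) {
    prior <- head_onsets[head_onsets <= to + 1e-9]
    if (!length(prior)) next
    h <- max(prior)
    d <- (to - h) * 1000
    if (d <= max_pair_gap_ms) delays <- c(delays, d)
  }
  list(delays_ms = delays,
       mean_delay_ms = if (length(delays)) mean(delays) else NA_real_,
       n_pairs = length(delays), empty = length(delays) == 0L)
}
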