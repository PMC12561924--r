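# Fixation and saccade detection on the eyes-in-space stream.
#
# Dispersion is defined on the sphere (maximum pairwise orthodromic distance
# within the window), not on the equirectangular map, so detection behaves
# identically at the equator and near the poles. The centroid of a fixation
# is the renormalized vector mean of its member gaze vectors, which avoids
# longitude-wraparound artifacts.

#' Detect fixations with a spherical dispersion-threshold algorithm
#'
#' Greedy left-to-right I-DT: a window of consecutive gaze samples grows
#' while the maximum pairwise great-circle distance among its members stays
#' within `dispersion_deg`; when a sample violates the threshold the window
#' is emitted as a fixation if it lasted at least `min_dur_ms`, and scanning
#' restarts at the violating sample. Ties therefore resolve toward the
#' longer, earlier-starting fixation. Samples flagged invalid (blinks,
#' dropouts) split windows and are never interpolated across.
#'
#' @param gaze data.frame with columns `t` (seconds) and `lon`, `lat`
#'   (degrees), time-ordered; optionally a logical column `valid`.
#' @param dispersion_deg spherical dispersion threshold (default 3).
#' @param min_dur_ms minimum fixation duration in ms (default 80).
#' @return data.frame with one row per fixation: `lon`, `lat` (centroid),
#'   `t_start`, `t_end` (seconds), `duration` (ms).
#' @export
detect_fixations <- function(gaze, dispersion_deg = 3, min_dur_ms = 80) {
  stopifnot(is.data.frame(gaze), all(c("t", "lon", "lat") %in% names(gaze)))
  if (nrow(gaze) == 0) return(empty_fixations())
  if (is.unsorted(gaze$t)) stop("detect_fixations: samples must be time-ordered")
  valid <- if ("valid" %in% names(gaze)) as.logical(gaze$valid) else rep(TRUE, nrow(gaze))
  valid[is.na(valid)] <- FALSE
  V <- lonlat_to_vec(gaze)
  win <- idt_windows(V, as.numeric(gaze$t), dispersion_deg, min_dur_ms / 1000, valid)
  if (nrow(win) == 0) return(empty_fixations())
  cent <- t(apply(win, 1, function(w) colMeans(V[w[1]:w[2], , drop = FALSE])))
  p <- vec_to_lonlat(cent)
  t_start <- gaze$t[win[, 1]]
  t_end <- gaze$t[win[, 2]]
  data.frame(lon = p$lon, lat = p$lat, t_start = t_start, t_end = t_end,
             duration = (t_end - t_start) * 1000)
}

empty_fixations <- function() {
  data.frame(lon = numeric(0), lat = numeric(0), t_start = numeric(0),
             t_end = numeric(0), duration = numeric(0))
}

#' Re-check emitted fixations against their defining invariants
#'
#' Independent post-hoc verifier: recomputes, from the raw gaze samples, the
#' exact maximum pairwise dispersion and the duration of every fixation.
#'
#' @param fixations output of [detect_fixations()].
#' @param gaze the gaze stream the fixations came from.
#' @inheritParams detect_fixations
#' @return logical vector, one entry per fixation; `TRUE` when the fixation
#'   satisfies both the dispersion and the duration invariant.
#' @export
verify_fixations <- function(fixations, gaze, dispersion_deg = 3, min_dur_ms = 80) {
  if (nrow(fixations) == 0) return(logical(0))
  V <- lonlat_to_vec(gaze)
  vapply(seq_len(nrow(fixations)), function(k) {
    idx <- which(gaze$t >= fixations$t_start[k] - 1e-12 &
                 gaze$t <= fixations$t_end[k] + 1e-12)
    disp <- max_pairwise_angle(V[idx, , drop = FALSE])
    disp <= dispersion_deg + 1e-9 &&
      fixations$duration[k] >= min_dur_ms - 1e-9
  }, logical(1))
}

#' Derive saccades from successive fixations
#'
#' One candidate saccade per adjacent fixation pair, characterised by the
#' orthodromic distance between the two centroids (amplitude) and the
#' inter-fixation gap (duration). Candidates whose gap exceeds
#' `max_dur_ms` are ignored: such long gaps are dominated by blinks or
#' tracking loss, not by a single rapid gaze shift.
#'
#' @param fixations time-ordered output of [detect_fixations()].
#' @param max_dur_ms maximum saccade duration in ms (default 300).
#' @return data.frame with one row per saccade: `lon_from`, `lat_from`,
#'   `lon_to`, `lat_to`, `t_start`, `t_end`, `amplitude` (degrees),
#'   `duration` (ms).
#' @export
derive_saccades <- function(fixations, max_dur_ms = 300) {
  n <- nrow(fixations)
  empty <- data.frame(lon_from = numeric(0), lat_from = numeric(0),
                      lon_to = numeric(0), lat_to = numeric(0),
                      t_start = numeric(0), t_end = numeric(0),
                      amplitude = numeric(0), duration = numeric(0))
  if (n < 2) return(empty)
  if (is.unsorted(fixations$t_start)) stop("derive_saccades: fixations must be time-ordered")
  a <- fixations[-n, ]
  b <- fixations[-1, ]
  gap_ms <- (b$t_start - a$t_end) * 1000
  keep <- gap_ms <= max_dur_ms + 1e-9
  if (!any(keep)) return(empty)
  a <- a[keep, ]; b <- b[keep, ]
  data.frame(lon_from = a$lon, lat_from = a$lat, lon_to = b$lon, lat_to = b$lat,
             t_start = a$t_end, t_end = b$t_start,
             amplitude = orthodromic(a[, c("lon", "lat")], b[, c("lon", "lat")]),
             duration = gap_ms[keep])
}
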