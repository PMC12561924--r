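# Trial logs and stream synchronization.
#
# A trial log is delimited text with one row per native sample and a stream
# tag column: `stream,t,ex,ey,ez,qw,qx,qy,qz,torso_yaw,chair_yaw`. Eye rows
# (250 Hz nominal) carry the eye-in-head unit vector; body rows (90 Hz
# nominal) carry the head quaternion plus torso and, in the swivel posture,
# chair yaw. Fields not native to a row's stream are left empty. Trial time
# zero is the first sample after the alignment fixation, so both the reader
# and the synthetic generator share one origin.

POSTURES <- c("sit", "swivel", "stand")
STIMULI <- c("indoor", "outdoor")

#' Construct a trial object
#'
#' Bundles the raw multi-rate streams with trial metadata. Streams are
#' validated (monotone time, unit norms within 1e-3) but kept at their
#' native rates until [synchronize()] is called.
#'
#' @param subject_id subject label.
#' @param posture one of `"sit"`, `"swivel"`, `"stand"`.
#' @param stimulus_type one of `"indoor"`, `"outdoor"`.
#' @param eye data.frame `t, ex, ey, ez` (eye-in-head unit vectors, 250 Hz
#'   nominal).
#' @param body data.frame `t, qw, qx, qy, qz, torso_yaw` and optionally
#'   `chair_yaw` (90 Hz nominal). A missing/NA chair yaw is structurally
#'   zero for sit and stand.
#' @param duration trial duration in seconds (default: span of the streams).
#' @return object of class `vr_trial`.
#' @export
vr_trial <- function(subject_id, posture, stimulus_type, eye, body,
                     duration = NULL) {
  posture <- match.arg(posture, POSTURES)
  stimulus_type <- match.arg(stimulus_type, STIMULI)
  stopifnot(all(c("t", "ex", "ey", "ez") %in% names(eye)),
            all(c("t", "qw", "qx", "qy", "qz", "torso_yaw") %in% names(body)))
  if (is.unsorted(eye$t, strictly = TRUE))
    stop("vr_trial: eye stream timestamps not strictly increasing")
  if (is.unsorted(body$t, strictly = TRUE))
    stop("vr_trial: body stream timestamps not strictly increasing")
  if (!("chair_yaw" %in% names(body)) || all(is.na(body$chair_yaw)))
    body$chair_yaw <- 0
  if (is.null(duration))
    duration <- max(c(eye$t, body$t)) - min(c(eye$t, body$t))
  structure(list(subject_id = subject_id, posture = posture,
                 stimulus_type = stimulus_type, duration = duration,
                 eye = eye, body = body, samples = NULL),
            class = "vr_trial")
}

#' @export
print.vr_trial <- function(x, ...) {
  cat(sprintf("<vr_trial> subject %s, %s posture, %s scene, %.1f s\n",
              x$subject_id, x$posture, x$stimulus_type, x$duration))
  cat(sprintf("  eye stream: %d samples; body stream: %d samples; %s\n",
              nrow(x$eye), nrow(x$body),
              if (is.null(x$samples)) "not synchronized"
              else sprintf("synchronized (%d samples)", nrow(x$samples))))
  invisible(x)
}

log_columns <- c("stream", "t", "ex", "ey", "ez", "qw", "qx", "qy", "qz",
                 "torso_yaw", "chair_yaw")

#' Write a trial to its delimited log format
#'
#' @param trial a `vr_trial`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trial, path) {
  eye <- data.frame(stream = "eye", t = trial$eye$t,
                    ex = trial$eye$ex, ey = trial$eye$ey, ez = trial$eye$ez,
                    qw = NA, qx = NA, qy = NA, qz = NA,
                    torso_yaw = NA, chair_yaw = NA)
  chair <- if (trial$posture == "swivel") trial$body$chair_yaw else NA
  body <- data.frame(stream = "body", t = trial$body$t,
                     ex = NA, ey = NA, ez = NA,
                     qw = trial$body$qw, qx = trial$body$qx,
                     qy = trial$body$qy, qz = trial$body$qz,
                     torso_yaw = trial$body$torso_yaw, chair_yaw = chair)
  rows <- rbind(eye, body)
  rows <- rows[order(rows$t, rows$stream), ]
  # full float round-trip precision
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], function(x) {
    out <- formatC(x, format = "g", digits = 17)
    out[is.na(x)] <- ""
    out
  })
  utils::write.table(rows, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a trial log
#'
#' Parses and validates one delimited trial log: the column schema must
#' match, timestamps must be strictly increasing per stream, quaternions and
#' eye vectors must be unit-norm within 1e-3, and no more than 5 percent of
#' rows may be invalid. Structured errors name the offending row.
#'
#' @param path log file path.
#' @param metadata list (or one-row data.frame) with `subject_id`,
#'   `posture`, `stimulus_type`.
#' @return a `vr_trial`.
#' @export
read_trial_log <- function(path, metadata) {
  if (!file.exists(path)) stop("read_trial_log: no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(raw), log_columns))
    stop("read_trial_log: column schema mismatch in ", path,
         " (expected ", paste(log_columns, collapse = ","), ")")
  metadata <- as.list(metadata)
  eye <- raw[raw$stream == "eye", c("t", "ex", "ey", "ez")]
  body <- raw[raw$stream == "body",
              c("t", "qw", "qx", "qy", "qz", "torso_yaw", "chair_yaw")]
  if (nrow(eye) == 0 || nrow(body) == 0)
    stop("read_trial_log: log must contain both an eye and a body stream")
  check_monotone <- function(t, stream) {
    bad <- which(diff(t) <= 0)
    if (length(bad))
      stop(sprintf("read_trial_log: non-monotone time in %s stream at row %d (t = %g)",
                   stream, bad[1] + 1L, t[bad[1] + 1L]))
  }
  check_monotone(eye$t, "eye")
  check_monotone(body$t, "body")
  eye_norm <- sqrt(eye$ex^2 + eye$ey^2 + eye$ez^2)
  bad_eye <- !is.finite(eye_norm) | abs(eye_norm - 1) > 1e-3
  q_norm <- sqrt(body$qw^2 + body$qx^2 + body$qy^2 + body$qz^2)
  bad_body <- !is.finite(q_norm) | abs(q_norm - 1) > 1e-3 |
    !is.finite(body$torso_yaw)
  frac_bad <- (sum(bad_eye) + sum(bad_body)) / (nrow(eye) + nrow(body))
  if (frac_bad > 0.05)
    stop(sprintf(paste0("read_trial_log: %.1f%% invalid samples (> 5%%); ",
                        "first bad row: %d"), 100 * frac_bad,
                 which(c(bad_eye, bad_body))[1]))
  if (any(bad_eye)) eye <- eye[!bad_eye, ]
  if (any(bad_body)) body <- body[!bad_body, ]
  rownames(eye) <- NULL
  rownames(body) <- NULL
  vr_trial(metadata$subject_id, metadata$posture, metadata$stimulus_type,
           eye = eye, body = body)
}

#' Write / read a trial-store manifest
#'
#' The manifest is a JSON array listing every trial log with its subject,
#' posture, and stimulus metadata, relative to the manifest's directory.
#'
#' @param trials data.frame with columns `file`, `subject_id`, `posture`,
#'   `stimulus_type`.
#' @param path manifest path.
#' @return `path` invisibly (write); the trials data.frame (read).
#' @export
write_manifest <- function(trials, path) {
  stopifnot(all(c("file", "subject_id", "posture", "stimulus_type") %in%
                  names(trials)))
  jsonlite::write_json(trials, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::fromJSON(path)
}

unwrap_deg <- function(x) {
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  c(x[1], x[1] + cumsum(d))
}

#' Synchronize the eye and body streams onto a common timebase
#'
#' Resamples every signal onto the eye-stream timestamps (the highest-rate
#' stream, so no eye-event timing is degraded) or onto a fixed-rate grid.
#' Head quaternions are interpolated by slerp, torso and chair yaw linearly
#' after unwrapping across the +/-180 meridian, and eye vectors linearly with
#' renormalization. Edges are clamped to the nearest sample. Synchronizing
#' an already-synchronized trial is a no-op.
#'
#' @param trial a `vr_trial`.
#' @param target_rate optional sampling rate in Hz; default uses the eye
#'   timestamps unchanged.
#' @param max_gap_ms largest tolerated gap inside either stream (default
#'   100 ms); a larger gap raises an error naming its location.
#' @return the trial with a `samples` data.frame
#'   (`t, ex, ey, ez, qw, qx, qy, qz, torso_yaw, chair_yaw`) attached.
#' @export
synchronize <- function(trial, target_rate = NULL, max_gap_ms = 100) {
  stopifnot(inherits(trial, "vr_trial"))
  if (!is.null(trial$samples) && is.null(target_rate)) return(trial)
  for (nm in c("eye", "body")) {
    gaps <- diff(trial[[nm]]$t)
    if (length(gaps) && max(gaps) > max_gap_ms / 1000)
      stop(sprintf("synchronize: %s stream gap of %.0f ms at t = %.3f s exceeds %g ms",
                   nm, 1000 * max(gaps), trial[[nm]]$t[which.max(gaps)], max_gap_ms))
  }
  tt <- if (is.null(target_rate)) trial$eye$t else {
    t0 <- min(trial$eye$t[1], trial$body$t[1])
    t1 <- max(trial$eye$t[nrow(trial$eye)], trial$body$t[nrow(trial$body)])
    seq(t0, t1, by = 1 / target_rate)
  }
  eye <- trial$eye
  if (is.null(target_rate)) {
    E <- cbind(eye$ex, eye$ey, eye$ez)
  } else {
    E <- cbind(stats::approx(eye$t, eye$ex, tt, rule = 2)$y,
               stats::approx(eye$t, eye$ey, tt, rule = 2)$y,
               stats::approx(eye$t, eye$ez, tt, rule = 2)$y)
  }
  E <- E / sqrt(rowSums(E^2))
  body <- trial$body
  Q <- quat_normalize(cbind(body$qw, body$qx, body$qy, body$qz))
  # hemisphere-align successive quaternions so slerp takes the short arc
  for (i in seq_len(nrow(Q) - 1)) {
    if (sum(Q[i, ] * Q[i + 1, ]) < 0) Q[i + 1, ] <- -Q[i + 1, ]
  }
  idx <- findInterval(tt, body$t, rightmost.closed = FALSE, all.inside = TRUE)
  f <- (tt - body$t[idx]) / (body$t[idx + 1] - body$t[idx])
  f <- pmin(pmax(f, 0), 1)                         # clamp edges
  Qs <- quat_slerp(Q[idx, , drop = FALSE], Q[idx + 1, , drop = FALSE], f)
  ty <- unwrap_deg(body$torso_yaw)
  torso <- wrap_lon(ty[idx] * (1 - f) + ty[idx + 1] * f)
  cy <- unwrap_deg(body$chair_yaw)
  chair <- wrap_lon(cy[idx] * (1 - f) + cy[idx + 1] * f)
  trial$samples <- data.frame(t = tt, ex = E[, 1], ey = E[, 2], ez = E[, 3],
                              qw = Qs[, 1], qx = Qs[, 2], qy = Qs[, 3],
                              qz = Qs[, 4], torso_yaw = torso,
                              chair_yaw = chair)
  trial
}

#' Gaze (eyes-in-space) stream of a synchronized trial
#'
#' Convenience accessor: integrates the synchronized eye-in-head vectors
#' with the head quaternions and returns the gaze point time series.
#'
#' @param trial a synchronized `vr_trial`.
#' @return data.frame `t`, `lon`, `lat`.
#' @export
gaze_stream <- function(trial) {
  s <- need_samples(trial)
  p <- integrate_gaze(cbind(s$ex, s$ey, s$ez), cbind(s$qw, s$qx, s$qy, s$qz))
  data.frame(t = s$t, lon = p$lon, lat = p$lat)
}

need_samples <- function(trial) {
  stopifnot(inherits(trial, "vr_trial"))
  if (is.null(trial$samples))
    stop("trial is not synchronized; call synchronize() first")
  trial$samples
}
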