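# End-to-end analysis pipeline: one trial in, events and frame summaries
# out; and a streaming study runner that never materialises more than one
# trial at a time.

#' Analysis parameters
#'
#' All detection and locking knobs in one place, at the study's values:
#' 3 deg dispersion / 80 ms minimum duration fixations, 300 ms maximum
#' saccade duration, 3 deg coverage radius, a [-400, 200] ms x 4 ms
#' saccade-locked eccentricity grid, and the 10 / 5 deg/s onset detector
#' with 5 deg minimum movement.
#'
#' @param dispersion_deg,min_dur_ms,max_sacc_dur_ms fixation/saccade rules.
#' @param theta_deg,coverage_resolution coverage estimator settings.
#' @param ecc_window_ms,ecc_bin_ms eccentricity locking grid.
#' @param vel_thresh,hyst_thresh,min_move_deg,onset_smooth_ms onset
#'   detector settings.
#' @param max_pair_gap_ms head-torso onset pairing window.
#' @param dead_band_deg_s head-direction split dead band.
#' @return list of class `analysis_params`.
#' @export
analysis_params <- function(dispersion_deg = 3, min_dur_ms = 80,
                            max_sacc_dur_ms = 300, theta_deg = 3,
                            coverage_resolution = 5e5,
                            ecc_window_ms = c(-400, 200), ecc_bin_ms = 4,
                            vel_thresh = 10, hyst_thresh = 5,
                            min_move_deg = 5, onset_smooth_ms = 50,
                            max_pair_gap_ms = 500, dead_band_deg_s = 5) {
  structure(as.list(environment()), class = "analysis_params")
}

#' Analyse one trial end to end
#'
#' Synchronizes the streams, integrates gaze, detects fixations and
#' saccades, and computes the per-trial exploration metrics, frame point
#' sets, saccade-locked eccentricity profile, and head/torso rotation
#' onsets.
#'
#' @param trial a `vr_trial` (synchronized or not).
#' @param params an [analysis_params()] list.
#' @param coverage compute the (comparatively expensive) grid coverage?
#' @return list: `trial`, `gaze`, `fixations`, `saccades`, `exploration`,
#'   `ecc_profile`, `head_onsets`, `torso_onsets`, `delay`.
#' @export
analyze_trial <- function(trial, params = analysis_params(), coverage = TRUE) {
  trial <- synchronize(trial)
  gaze <- gaze_stream(trial)
  fix <- detect_fixations(gaze, params$dispersion_deg, params$min_dur_ms)
  sacc <- derive_saccades(fix, params$max_sacc_dur_ms)
  expl <- data.frame(total_distance = total_distance(sacc),
                     coverage = if (coverage)
                       coverage_percent(fix, params$theta_deg,
                                        params$coverage_resolution) else NA_real_,
                     n_fixations = nrow(fix),
                     mean_fix_dur = if (nrow(fix)) mean(fix$duration) else NA_real_)
  ecc <- eccentricity_series(trial)
  prof <- lock_to_saccade_starts(ecc, sacc, params$ecc_window_ms,
                                 params$ecc_bin_ms)
  head_lon <- frame_points(trial, "head_in_space")$lon
  s <- trial$samples
  h_on <- detect_rotation_onsets(s$t, head_lon, params$vel_thresh,
                                 params$hyst_thresh, params$min_move_deg,
                                 params$onset_smooth_ms)
  t_on <- detect_rotation_onsets(s$t, s$torso_yaw, params$vel_thresh,
                                 params$hyst_thresh, params$min_move_deg,
                                 params$onset_smooth_ms)
  delay <- head_torso_delay(h_on, t_on, params$max_pair_gap_ms)
  list(trial = trial, gaze = gaze, fixations = fix, saccades = sacc,
       exploration = expl, ecc_profile = prof,
       head_onsets = h_on, torso_onsets = t_on, delay = delay)
}

#' Run a full synthetic study through the pipeline
#'
#' Generates every trial of the crossed design and streams it through
#' [analyze_trial()], accumulating: trial-level exploration metrics,
#' fixation-level eyes-in-space points, per-subject first/second moments of
#' every sample-level effector frame, 1-degree longitude histograms per
#' frame and posture (for the bimodality analyses), pooled saccade-locked
#' eccentricity profiles per posture, head-torso onset delays, and the
#' eyes-in-head means conditional on head movement direction.
#'
#' @param config a `generator_config`.
#' @param profiles named list of posture profiles.
#' @param params an [analysis_params()] list.
#' @param coverage compute grid coverage per trial (off by default for
#'   large designs; the coverage estimator has its own analyses).
#' @param progress print a line every 100 trials.
#' @return list of class `study_results`; see Details in the source.
#' @export
run_study <- function(config, profiles = default_profiles(),
                      params = analysis_params(), coverage = FALSE,
                      progress = FALSE) {
  dx <- experiment_design(config, profiles)
  d <- dx$design
  frames_sample <- c("head_in_space", "torso_in_space", "eyes_in_head",
                     "head_rel_torso")
  bin_edges <- seq(-180, 180, by = 1)
  bin_mid <- bin_edges[-1] - 0.5

  metrics <- vector("list", nrow(d))
  fix_pts <- vector("list", nrow(d))
  delays <- vector("list", nrow(d))
  moments <- new.env(parent = emptyenv())
  hist_acc <- new.env(parent = emptyenv())
  ecc_acc <- list()
  headdir <- new.env(parent = emptyenv())

  add_moments <- function(key, lon, lat) {
    cur <- moments[[key]]
    add <- c(length(lon), sum(lon), sum(lon^2), sum(lat), sum(lat^2))
    moments[[key]] <- if (is.null(cur)) add else cur + add
  }
  add_hist <- function(key, lon) {
    cur <- hist_acc[[key]]
    cnt <- tabulate(findInterval(wrap_lon(lon), bin_edges,
                                 rightmost.closed = TRUE), 360)
    hist_acc[[key]] <- if (is.null(cur)) cnt else cur + cnt
  }

  for (i in seq_len(nrow(d))) {
    pr <- dx$profiles[[d$subject_id[i]]][[d$posture[i]]]
    trial <- generate_trial(pr, config, seed = d$seed[i],
                            stimulus_type = d$stimulus_type[i],
                            subject_id = d$subject_id[i])
    an <- analyze_trial(trial, params, coverage = coverage)
    metrics[[i]] <- cbind(d[i, c("subject_id", "posture", "stimulus_type",
                                 "trial")], an$exploration)
    if (nrow(an$fixations))
      fix_pts[[i]] <- data.frame(subject_id = d$subject_id[i],
                                 posture = d$posture[i],
                                 stimulus_type = d$stimulus_type[i],
                                 lon = an$fixations$lon,
                                 lat = an$fixations$lat)
    for (fr in frames_sample) {
      fp <- frame_points(an$trial, fr)
      add_moments(paste(d$subject_id[i], d$posture[i], fr, sep = "|"),
                  fp$lon, fp$lat)
      add_hist(paste(d$posture[i], fr, sep = "|"), fp$lon)
    }
    if (d$posture[i] == "swivel") {
      fp <- frame_points(an$trial, "torso_rel_chair")
      add_moments(paste(d$subject_id[i], "swivel", "torso_rel_chair", sep = "|"),
                  fp$lon, fp$lat)
      add_hist("swivel|torso_rel_chair", fp$lon)
    }
    po <- d$posture[i]
    ecc_acc[[po]] <- if (is.null(ecc_acc[[po]])) an$ecc_profile
                     else pool_ecc_profiles(list(ecc_acc[[po]], an$ecc_profile))
    if (an$delay$n_pairs > 0)
      delays[[i]] <- data.frame(subject_id = d$subject_id[i], posture = po,
                                trial = d$trial[i],
                                delay_ms = an$delay$delays_ms)
    sp <- split_by_head_direction(an$trial, params$dead_band_deg_s)
    for (side in c("rightward", "leftward")) {
      key <- paste(po, side, sep = "|")
      cur <- headdir[[key]]
      add <- c(nrow(sp[[side]]), sum(sp[[side]]$lon))
      headdir[[key]] <- if (is.null(cur)) add else cur + add
    }
    if (progress && i %% 100 == 0)
      message(sprintf("  trial %d / %d", i, nrow(d)))
  }

  mom_keys <- ls(moments)
  mom_parts <- strsplit(mom_keys, "|", fixed = TRUE)
  mom_df <- data.frame(subject_id = vapply(mom_parts, `[`, "", 1),
                       condition = vapply(mom_parts, `[`, "", 2),
                       frame = vapply(mom_parts, `[`, "", 3))
  mm <- t(vapply(mom_keys, function(k) moments[[k]], numeric(5)))
  mom_df$n <- mm[, 1]; mom_df$sum_lon <- mm[, 2]; mom_df$sum_lon2 <- mm[, 3]
  mom_df$sum_lat <- mm[, 4]; mom_df$sum_lat2 <- mm[, 5]

  hist_keys <- ls(hist_acc)
  hp <- strsplit(hist_keys, "|", fixed = TRUE)
  lon_hist <- do.call(rbind, lapply(seq_along(hist_keys), function(k)
    data.frame(posture = hp[[k]][1], frame = hp[[k]][2], lon = bin_mid,
               count = hist_acc[[hist_keys[k]]])))

  hd_keys <- ls(headdir)
  hd <- strsplit(hd_keys, "|", fixed = TRUE)
  headdir_df <- do.call(rbind, lapply(seq_along(hd_keys), function(k)
    data.frame(posture = hd[[k]][1], side = hd[[k]][2],
               n = headdir[[hd_keys[k]]][1],
               mean_lon = headdir[[hd_keys[k]]][2] /
                 max(headdir[[hd_keys[k]]][1], 1))))

  structure(list(config = config,
                 trial_metrics = do.call(rbind, metrics),
                 fix_points = do.call(rbind, fix_pts),
                 frame_moments = mom_df,
                 lon_hist = lon_hist,
                 ecc_profiles = ecc_acc,
                 delays = do.call(rbind, delays),
                 headdir = headdir_df),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results> %d trials (%d subjects x %d postures)\n",
              nrow(x$trial_metrics), length(unique(x$trial_metrics$subject_id)),
              length(unique(x$trial_metrics$posture))))
  invisible(x)
}

#' Condition-level summaries of a study run
#'
#' Collapses a [run_study()] result into the statistics the posture
#' comparison rests on: eyes-in-space fixation spreads, sample-level frame
#' spreads and latitude biases, eccentricity minima, and mean head-torso
#' onset delays, each per posture.
#'
#' @param res a `study_results` object.
#' @return list of data.frames / named vectors; see element names.
#' @export
summarize_study <- function(res) {
  fp <- res$fix_points
  fp$condition <- fp$posture
  gaze_spread <- spread_stats(fp)
  frame_spread <- lapply(split(res$frame_moments, res$frame_moments$frame),
                         spread_from_moments)
  ecc_min <- vapply(res$ecc_profiles, function(p) p$min_ecc, numeric(1))
  delay <- if (!is.null(res$delays))
    stats::aggregate(delay_ms ~ posture, data = res$delays, FUN = mean)
  else NULL
  list(gaze_spread = gaze_spread, frame_spread = frame_spread,
       ecc_min = ecc_min, delay = delay)
}
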