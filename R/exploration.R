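# Per-trial exploration metrics: total gaze travel and overlap-corrected
# spherical-cap coverage.

.grid_cache <- new.env(parent = emptyenv())

#' Total gaze travel distance of a trial
#'
#' Sum of the saccade amplitudes, in degrees of great-circle arc.
#'
#' @param saccades output of [derive_saccades()] for one trial.
#' @return total distance in degrees (0 for an empty sequence).
#' @export
total_distance <- function(saccades) {
  if (nrow(saccades) == 0) return(0)
  sum(saccades$amplitude)
}

#' Percentage of the view sphere covered by fixations
#'
#' Area of the union of spherical caps of angular radius `theta_deg` around
#' all fixation centroids, as percent of the full sphere. Because adjacent
#' fixation areas overlap, the union is evaluated on a Fibonacci-lattice
#' near-equal-area grid: a cell counts as covered when its centre lies
#' within `theta_deg` of any centroid, and the covered cell fraction is the
#' coverage. At the default resolution of 500,000 cells each cell carries
#' 0.0002 percent of the sphere, giving a single 3-degree cap (analytically
#' 0.06852 percent) to well within 2 percent relative error.
#'
#' @param fixations data.frame with centroid `lon`, `lat` columns.
#' @param theta_deg cap radius in degrees; defaults to the fixation
#'   dispersion radius (3).
#' @param resolution number of grid cells (default 5e5).
#' @return coverage in percent of the sphere.
#' @export
coverage_percent <- function(fixations, theta_deg = 3, resolution = 5e5) {
  if (!is.finite(theta_deg) || theta_deg <= 0)
    stop("coverage_percent: theta_deg must be positive")
  if (nrow(fixations) == 0) return(0)
  key <- paste0("g", resolution)
  if (is.null(.grid_cache[[key]]))
    .grid_cache[[key]] <- fibonacci_grid(resolution)
  G <- .grid_cache[[key]]
  C <- lonlat_to_vec(fixations[, c("lon", "lat")])
  cos_t <- cos(theta_deg * pi / 180)
  best <- rep(-1, nrow(G))
  for (k in seq_len(nrow(C))) {
    best <- pmax(best, G %*% C[k, ])
  }
  100 * mean(best >= cos_t)
}

#' Exploration summary of one trial
#'
#' @param fixations,saccades event tables of one trial.
#' @inheritParams coverage_percent
#' @return one-row data.frame: `total_distance` (deg), `coverage` (percent),
#'   `n_fixations`, `mean_fix_dur` (ms).
#' @export
trial_exploration <- function(fixations, saccades, theta_deg = 3,
                              resolution = 5e5) {
  data.frame(total_distance = total_distance(saccades),
             coverage = coverage_percent(fixations, theta_deg, resolution),
             n_fixations = nrow(fixations),
             mean_fix_dur = if (nrow(fixations)) mean(fixations$duration) else NA_real_)
}
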