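#' @useDynLib spheregaze, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx density filter qt pt sd setNames aggregate
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# Axis convention (fixed once, enforced by tests):
#   +x = forward (lon 0, lat 0), +y = east/right (lon +90), +z = up (lat +90).
# Right-handed; a positive yaw about +z turns the forward axis rightward.
# Longitude lives in [-180, 180) (half-open); at the poles lon is
# canonicalised to 0. All angles are degrees unless a name says otherwise.

DEG <- pi / 180

#' Normalize longitudes into [-180, 180)
#'
#' Wrapped-angle arithmetic helper: `lon` and `lon + 360` map to the same
#' value, with +180 folded to -180 so the range is half-open.
#'
#' @param lon numeric vector of angles in degrees.
#' @return numeric vector in `[-180, 180)`.
#' @export
wrap_lon <- function(lon) {
  w <- ((lon + 180) %% 360) - 180
  # %% can return 360 - eps for tiny negative fuzz; fold exactly
  w[w >= 180] <- w[w >= 180] - 360
  w
}

#' Construct view-sphere points
#'
#' A sphere point is a longitude/latitude pair on the unit view-sphere
#' surrounding the observer. Longitudes are wrapped into `[-180, 180)` and a
#' point at either pole gets longitude 0 so every location has one canonical
#' representation.
#'
#' @param lon,lat numeric vectors, degrees. `lat` must lie in `[-90, 90]`.
#' @return data.frame with columns `lon`, `lat`.
#' @export
sphere_point <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("sphere_point: non-finite coordinates")
  if (any(lat < -90 - 1e-9 | lat > 90 + 1e-9))
    stop("sphere_point: latitude outside [-90, 90]")
  lat <- pmin(pmax(lat, -90), 90)
  lon <- wrap_lon(lon)
  lon[abs(lat) >= 90 - 1e-12] <- 0
  data.frame(lon = unname(lon), lat = unname(lat))
}

#' Convert lon/lat points to unit direction vectors
#'
#' Forward (0, 0) maps to +x, (90, 0) to +y (east/right), (0, 90) to +z (up).
#'
#' @param p data.frame with `lon`, `lat` in degrees (or a length-2 numeric
#'   `c(lon, lat)`).
#' @return n x 3 matrix of unit vectors, columns `x`, `y`, `z`.
#' @export
lonlat_to_vec <- function(p) {
  p <- as_point(p)
  cl <- cos(p$lat * DEG)
  v <- cbind(x = cl * cos(p$lon * DEG),
             y = cl * sin(p$lon * DEG),
             z = sin(p$lat * DEG))
  v
}

#' Convert unit vectors to lon/lat points
#'
#' Inverse of [lonlat_to_vec()]. Inputs are renormalized, so any nonzero
#' vector is accepted; a zero (or near-zero) vector is an error. Pole outputs
#' are canonicalised to lon 0.
#'
#' @param v n x 3 numeric matrix (or length-3 vector) of directions.
#' @return data.frame with columns `lon`, `lat` in degrees.
#' @export
vec_to_lonlat <- function(v) {
  v <- as_vec3(v)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-12)) stop("vec_to_lonlat: zero-length direction vector")
  v <- v / nrm
  lat <- asin(pmin(pmax(unname(v[, 3]), -1), 1)) / DEG
  lon <- atan2(unname(v[, 2]), unname(v[, 1])) / DEG
  sphere_point(lon, lat)
}

as_point <- function(p) {
  if (is.numeric(p) && length(p) == 2L) p <- data.frame(lon = p[1], lat = p[2])
  if (is.matrix(p)) p <- data.frame(lon = p[, 1], lat = p[, 2])
  stopifnot(is.data.frame(p), all(c("lon", "lat") %in% names(p)))
  p
}

as_vec3 <- function(v) {
  if (is.numeric(v) && is.null(dim(v)) && length(v) == 3L) v <- matrix(v, 1)
  stopifnot(is.matrix(v) || is.data.frame(v))
  v <- as.matrix(v)
  stopifnot(ncol(v) == 3L)
  v
}

#' Great-circle (orthodromic) distance between sphere points
#'
#' Central angle of the shortest arc connecting two points on the view
#' sphere, in degrees. Computed with the numerically stable atan2 form, which
#' keeps full precision for both near-coincident and near-antipodal pairs.
#' Arguments recycle elementwise.
#'
#' @param p1,p2 sphere points (data.frame `lon`/`lat` or `c(lon, lat)`).
#' @return numeric vector of angles in `[0, 180]` degrees.
#' @export
orthodromic <- function(p1, p2) {
  v1 <- lonlat_to_vec(as_point(p1))
  v2 <- lonlat_to_vec(as_point(p2))
  n <- max(nrow(v1), nrow(v2))
  if (nrow(v1) < n) v1 <- v1[rep_len(seq_len(nrow(v1)), n), , drop = FALSE]
  if (nrow(v2) < n) v2 <- v2[rep_len(seq_len(nrow(v2)), n), , drop = FALSE]
  dotp <- rowSums(v1 * v2)
  crs <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
               v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
               v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  unname(atan2(sqrt(rowSums(crs^2)), dotp)) / DEG
}

# angle between rows of two unit-vector matrices (degrees)
vec_angle <- function(v1, v2) {
  dotp <- rowSums(v1 * v2)
  crs <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
               v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
               v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  atan2(sqrt(rowSums(crs^2)), dotp) / DEG
}

#' Spherical-cap area fraction
#'
#' Fraction of the view sphere, in percent, lying within angular radius
#' `theta` of a point: `50 * (1 - cos(theta))`. A cap of radius 3 degrees
#' covers 0.06852 percent of the sphere; 90 degrees is a hemisphere (50
#' percent) and 180 degrees the full sphere.
#'
#' @param theta angular radius in degrees, in `[0, 180]`.
#' @return percent of the sphere's surface area.
#' @export
cap_fraction <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 180))
    stop("cap_fraction: theta must lie in [0, 180] degrees")
  50 * (1 - cos(theta * DEG))
}

#' Equirectangular bin index of sphere points
#'
#' Uniform longitude/latitude binning of the equirectangular map. Longitude
#' bins wrap at the +/-180 meridian, so lon = -180 and lon just below +180
#' land in adjacent bins modulo `n_lon`. Bin indices are 1-based.
#'
#' @param p sphere points.
#' @param n_lon,n_lat number of bins along longitude and latitude (>= 1).
#' @return data.frame with integer columns `i_lon`, `i_lat`.
#' @export
equirect_bin <- function(p, n_lon, n_lat) {
  stopifnot(n_lon >= 1, n_lat >= 1)
  p <- as_point(sphere_point(as_point(p)$lon, as_point(p)$lat))
  i_lon <- pmin(floor((p$lon + 180) / 360 * n_lon), n_lon - 1) + 1L
  i_lat <- pmin(floor((p$lat + 90) / 180 * n_lat), n_lat - 1) + 1L
  data.frame(i_lon = as.integer(i_lon), i_lat = as.integer(i_lat))
}

#' Fibonacci-lattice sampling of the sphere
#'
#' Near-equal-area deterministic grid used by the coverage estimator: point i
#' of n sits at height z = 1 - (2i+1)/n with longitudes advancing by the
#' golden angle, so every cell carries weight 1/n with no pole pathology.
#'
#' @param n number of grid points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_grid <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

## ---- quaternions -----------------------------------------------------------
## Scalar-first unit quaternions (w, x, y, z) representing world-from-head
## rotations. q and -q denote the same rotation; every ingestion path
## renormalizes and rejects norms off by more than 1e-3.

as_quat <- function(q) {
  if (is.numeric(q) && is.null(dim(q)) && length(q) == 4L) q <- matrix(q, 1)
  q <- as.matrix(q)
  stopifnot(ncol(q) == 4L)
  q
}

#' Renormalize quaternions, rejecting badly non-unit inputs
#'
#' @param q n x 4 matrix (or length-4 vector), scalar-first `(w, x, y, z)`.
#' @param tol maximum tolerated deviation of the norm from 1 before
#'   renormalization (default 1e-3).
#' @return n x 4 matrix of unit quaternions.
#' @export
quat_normalize <- function(q, tol = 1e-3) {
  q <- as_quat(q)
  nrm <- sqrt(rowSums(q^2))
  if (any(abs(nrm - 1) > tol))
    stop("quat_normalize: quaternion norm deviates from 1 by more than ", tol)
  q / nrm
}

#' Hamilton product of quaternions
#'
#' Rowwise product `q1 * q2` (apply `q2`'s rotation first, then `q1`'s).
#'
#' @param q1,q2 n x 4 scalar-first quaternion matrices (rows recycle).
#' @return n x 4 matrix.
#' @export
quat_multiply <- function(q1, q2) {
  q1 <- as_quat(q1); q2 <- as_quat(q2)
  n <- max(nrow(q1), nrow(q2))
  if (nrow(q1) < n) q1 <- q1[rep_len(seq_len(nrow(q1)), n), , drop = FALSE]
  if (nrow(q2) < n) q2 <- q2[rep_len(seq_len(nrow(q2)), n), , drop = FALSE]
  w1 <- q1[, 1]; x1 <- q1[, 2]; y1 <- q1[, 3]; z1 <- q1[, 4]
  w2 <- q2[, 1]; x2 <- q2[, 2]; y2 <- q2[, 3]; z2 <- q2[, 4]
  cbind(w = w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
        x = w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
        y = w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
        z = w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

#' Rotate vectors by quaternions
#'
#' Applies the rotation encoded by each row of `q` to the matching row of
#' `v` (`q v q*`). Rows recycle, so one quaternion can rotate many vectors.
#'
#' @param q n x 4 scalar-first unit quaternions.
#' @param v n x 3 vectors.
#' @return n x 3 matrix of rotated vectors.
#' @export
quat_rotate <- function(q, v) {
  q <- as_quat(q); v <- as_vec3(v)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) < n) q <- q[rep_len(seq_len(nrow(q)), n), , drop = FALSE]
  if (nrow(v) < n) v <- v[rep_len(seq_len(nrow(v)), n), , drop = FALSE]
  w <- q[, 1]; u <- q[, 2:4, drop = FALSE]
  # t = 2 u x v ; v' = v + w t + u x t
  tx <- 2 * (u[, 2] * v[, 3] - u[, 3] * v[, 2])
  ty <- 2 * (u[, 3] * v[, 1] - u[, 1] * v[, 3])
  tz <- 2 * (u[, 1] * v[, 2] - u[, 2] * v[, 1])
  cbind(x = v[, 1] + w * tx + u[, 2] * tz - u[, 3] * ty,
        y = v[, 2] + w * ty + u[, 3] * tx - u[, 1] * tz,
        z = v[, 3] + w * tz + u[, 1] * ty - u[, 2] * tx)
}

#' Quaternion from yaw and pitch
#'
#' Builds the world-from-head rotation for a head yawed `yaw` degrees to the
#' right (about +z) and pitched `pitch` degrees upward, with no roll:
#' the head-forward axis maps to lon = yaw, lat = pitch.
#'
#' @param yaw,pitch numeric vectors, degrees.
#' @return n x 4 scalar-first quaternion matrix.
#' @export
quat_from_yaw_pitch <- function(yaw, pitch) {
  hy <- yaw * DEG / 2
  hp <- -pitch * DEG / 2            # pitch-up is a negative rotation about +y
  qz <- cbind(cos(hy), 0, 0, sin(hy))
  qy <- cbind(cos(hp), 0, sin(hp), 0)
  quat_multiply(qz, qy)
}

#' Spherical linear interpolation between successive quaternions
#'
#' Geodesic (constant angular velocity) interpolation used when upsampling a
#' low-rate orientation stream. Antipodal sign flips are resolved first so
#' the short arc is always taken; exactly parallel endpoints fall back to
#' linear interpolation.
#'
#' @param q1,q2 n x 4 unit quaternions (rows recycle).
#' @param f interpolation fraction(s) in `[0, 1]`.
#' @return n x 4 matrix of unit quaternions.
#' @export
quat_slerp <- function(q1, q2, f) {
  q1 <- as_quat(q1); q2 <- as_quat(q2)
  n <- max(nrow(q1), nrow(q2), length(f))
  if (nrow(q1) < n) q1 <- q1[rep_len(seq_len(nrow(q1)), n), , drop = FALSE]
  if (nrow(q2) < n) q2 <- q2[rep_len(seq_len(nrow(q2)), n), , drop = FALSE]
  f <- rep_len(f, n)
  d <- rowSums(q1 * q2)
  flip <- d < 0
  q2[flip, ] <- -q2[flip, , drop = FALSE]
  d <- abs(d)
  d <- pmin(d, 1)
  ang <- acos(d)
  s <- sin(ang)
  w1 <- ifelse(s > 1e-9, sin((1 - f) * ang) / s, 1 - f)
  w2 <- ifelse(s > 1e-9, sin(f * ang) / s, f)
  out <- q1 * w1 + q2 * w2
  out / sqrt(rowSums(out^2))
}

#' Combine eye-in-head direction with head orientation into gaze
#'
#' Rotates the eye-in-head unit vector by the world-from-head quaternion and
#' intersects the result with the view sphere, yielding the eyes-in-space
#' ("gaze") point. With an identity head orientation this reduces to
#' [vec_to_lonlat()] of the eye vector; `q` and `-q` give identical output.
#'
#' @param eye_in_head n x 3 unit vectors (eye direction in the head frame).
#' @param head n x 4 scalar-first unit quaternions (world from head).
#' @return data.frame of gaze points (`lon`, `lat`).
#' @export
integrate_gaze <- function(eye_in_head, head) {
  v <- as_vec3(eye_in_head)
  nrm <- sqrt(rowSums(v^2))
  if (any(abs(nrm - 1) > 1e-3))
    stop("integrate_gaze: eye vectors deviate from unit norm by more than 1e-3")
  v <- v / nrm
  q <- quat_normalize(head)
  vec_to_lonlat(quat_rotate(q, v))
}
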