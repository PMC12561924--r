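# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: haversine trigonometry instead of
# vector cross products, an O(n^2 w) from-scratch windowing re-check
# instead of the incremental detector, explicit rotation matrices instead
# of quaternion algebra, and Monte-Carlo instead of lattice integration.

# great-circle angle in degrees via the haversine formula
haversine_deg <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  2 * asin(pmin(sqrt(a), 1)) / r
}

# 3x3 rotation matrix of a scalar-first unit quaternion
rotmat_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# random unit quaternion
random_quat <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

# brute-force greedy dispersion-threshold windowing: same scheduling rule as
# the detector (restart at the first violating sample) but the dispersion of
# every candidate window is recomputed from scratch with the haversine
# oracle over all pairs
brute_idt <- function(gaze, dispersion_deg = 3, min_dur_ms = 80) {
  n <- nrow(gaze)
  disp_of <- function(idx) {
    if (length(idx) < 2) return(0)
    m <- 0
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in (i + 1):length(idx)) {
        d <- haversine_deg(gaze$lon[idx[i]], gaze$lat[idx[i]],
                           gaze$lon[idx[j]], gaze$lat[idx[j]])
        if (d > m) m <- d
      }
    }
    m
  }
  out <- NULL
  s <- 1L
  j <- s
  while (j < n) {
    j <- j + 1L
    if (disp_of(s:j) > dispersion_deg) {
      if (gaze$t[j - 1] - gaze$t[s] >= min_dur_ms / 1000 - 1e-12)
        out <- rbind(out, c(s, j - 1L))
      s <- j
    }
  }
  if (s < n && gaze$t[n] - gaze$t[s] >= min_dur_ms / 1000 - 1e-12)
    out <- rbind(out, c(s, n))
  out
}

# Monte-Carlo estimate of the union-of-caps area fraction (percent) with
# its standard error
mc_cap_union <- function(centroids, theta_deg = 3, n = 1e6) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  P <- cbind(r * cos(phi), r * sin(phi), z)
  C <- lonlat_to_vec(centroids[, c("lon", "lat")])
  cos_t <- cos(theta_deg * pi / 180)
  best <- rep(-1, n)
  for (k in seq_len(nrow(C))) best <- pmax(best, P %*% C[k, ])
  p <- mean(best >= cos_t)
  list(percent = 100 * p, se = 100 * sqrt(p * (1 - p) / n))
}

# one-way within-subject ANOVA by explicit sums-of-squares decomposition
hand_rm_anova_1w <- function(mat) {   # rows = subjects, cols = levels
  ns <- nrow(mat); nl <- ncol(mat)
  grand <- mean(mat)
  lvl <- colMeans(mat)
  subj <- rowMeans(mat)
  ss_eff <- ns * sum((lvl - grand)^2)
  resid <- mat - outer(subj, rep(1, nl)) - outer(rep(1, ns), lvl) + grand
  ss_err <- sum(resid^2)
  df1 <- nl - 1
  df2 <- (ns - 1) * (nl - 1)
  ss_sub <- nl * sum((subj - grand)^2)
  list(F = (ss_eff / df1) / (ss_err / df2), df1 = df1, df2 = df2,
       ss_eff = ss_eff, ss_err = ss_err, ss_sub = ss_sub,
       etaG2 = ss_eff / (ss_eff + ss_err + ss_sub))
}
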