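#include <Rcpp.h>
using namespace Rcpp;

// Greedy spherical dispersion-threshold (I-DT) fixation detection.
//
// The window [s..j] grows while the maximum pairwise great-circle angle of
// its member gaze vectors stays within the dispersion threshold. The maximum
// is maintained incrementally: adding sample j can only create new pairs
// (i, j), so one pass over the window per sample keeps it exact. When sample
// j violates the threshold the window [s..j-1] is emitted as a fixation if
// it lasts at least min_dur, and scanning restarts at j (the first violating
// sample). Samples flagged invalid split windows and belong to none.
//
// V: n x 3 unit gaze vectors, t: seconds, disp: degrees, min_dur: seconds.
// Returns integer matrix of 1-based [start, end] sample indices.
// [[Rcpp::export]]
IntegerMatrix idt_windows(NumericMatrix V, NumericVector t,
                          double disp, double min_dur, LogicalVector valid) {
  const int n = V.nrow();
  const double cos_disp = std::cos(disp * M_PI / 180.0);
  std::vector<int> starts, ends;

  auto dot = [&](int a, int b) {
    return V(a, 0) * V(b, 0) + V(a, 1) * V(b, 1) + V(a, 2) * V(b, 2);
  };
  auto emit = [&](int s, int e) {
    if (e > s && t[e] - t[s] >= min_dur - 1e-12) {
      starts.push_back(s + 1);
      ends.push_back(e + 1);
    } else if (e == s && min_dur <= 1e-12) {
      starts.push_back(s + 1);
      ends.push_back(e + 1);
    }
  };

  int s = 0;
  while (s < n && !valid[s]) ++s;
  int j = s;
  while (j < n) {
    ++j;
    if (j >= n) break;
    if (!valid[j]) {                 // dropout: close window, skip ahead
      emit(s, j - 1);
      s = j + 1;
      while (s < n && !valid[s]) ++s;
      j = s;
      continue;
    }
    bool ok = true;
    for (int i = s; i < j; ++i) {
      if (dot(i, j) < cos_disp) { ok = false; break; }
    }
    if (!ok) {                       // j violates: window ends at j-1
      emit(s, j - 1);
      s = j;
    }
  }
  if (s < n && s < (int)t.size()) emit(s, n - 1);

  IntegerMatrix out(starts.size(), 2);
  for (size_t k = 0; k < starts.size(); ++k) {
    out(k, 0) = starts[k];
    out(k, 1) = ends[k];
  }
  colnames(out) = CharacterVector::create("start", "end");
  return out;
}

// Exact maximum pairwise great-circle angle (degrees) of a set of unit
// vectors; the post-hoc dispersion verifier for emitted fixations.
// [[Rcpp::export]]
double max_pairwise_angle(NumericMatrix V) {
  const int n = V.nrow();
  double mind = 1.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = V(i, 0) * V(j, 0) + V(i, 1) * V(j, 1) + V(i, 2) * V(j, 2);
      if (d < mind) mind = d;
    }
  if (mind > 1.0) mind = 1.0;
  if (mind < -1.0) mind = -1.0;
  return std::acos(mind) * 180.0 / M_PI;
}

// First-order yaw tracking with per-sample gain and a neck-range cap
// relative to a reference (torso) series: the drive target is clamped to
// ref +/- cap_target and the head position itself to ref +/- cap_hard.
// alpha is the per-sample discrete tracking gain (1 - exp(-w dt / tau)).
// [[Rcpp::export]]
NumericVector track_yaw(NumericVector tgt, NumericVector ref,
                        NumericVector alpha, double cap_target,
                        double cap_hard, double init) {
  const int n = tgt.size();
  NumericVector out(n);
  double h = init;
  for (int i = 0; i < n; ++i) {
    double tg = tgt[i];
    if (tg > ref[i] + cap_target) tg = ref[i] + cap_target;
    if (tg < ref[i] - cap_target) tg = ref[i] - cap_target;
    h += alpha[i] * (tg - h);
    if (h > ref[i] + cap_hard) h = ref[i] + cap_hard;
    if (h < ref[i] - cap_hard) h = ref[i] - cap_hard;
    out[i] = h;
  }
  return out;
}
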