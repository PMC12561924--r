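---
title: "Methods: spherical gaze analysis and the posture-conditioned stream generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spherical gaze analysis and the posture-conditioned stream generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheregaze)
```

# The analysis problem

A person inside a 360° panorama orients with a nested chain of effectors:
the eyes rotate in the head, the head on the torso, the torso on the chair
or the feet. An eye tracker embedded in a VR headset measures the eye
direction *in the head frame* at 250 Hz; the headset and body trackers
measure head orientation (a quaternion) and torso/chair yaw at 90 Hz.
Everything this package computes starts from fusing those streams into
world coordinates on the unit **view sphere**, with positions expressed as
longitude in [−180°, 180°) and latitude in [−90°, 90°].

`spheregaze` implements that fusion and the analyses that sit on top of
it: spherical fixation and saccade detection, exploration metrics (gaze
travel and overlap-corrected scene coverage), longitude/latitude
distributions of every frame in the effector hierarchy, eye–head–torso
coordination dynamics, and the repeated-measures group statistics used to
compare posture conditions (sitting in a fixed chair, sitting in a swivel
chair, standing). Because no raw recordings ship with the package, a
synthetic generator produces posture-conditioned streams with the same
nested structure; the test suite demonstrates that the full pipeline
recovers the generator's configured parameters.

# Coordinate conventions

One convention is fixed once and enforced by tests: **+x is forward**
(lon 0, lat 0), **+y is east/right** (lon +90), **+z is up** (lat +90), a
right-handed frame in which a positive yaw about +z turns the forward axis
rightward. Quaternions are scalar-first (w, x, y, z), renormalized on
ingestion and rejected if their norm deviates by more than 10⁻³; q and −q
are the same rotation and produce identical results. Longitude is
canonicalised to the half-open interval [−180, 180) and the poles to
longitude 0. Distances are always great-circle (orthodromic) angles
computed on the sphere itself — never on the equirectangular map, whose
areas are badly distorted near the poles.

The hardware never reports its engine's axis convention in the analyses we
reproduce; any consistent convention yields identical statistics, so the
choice above is a definition, not an inference.

# Stream synchronization

The common timebase is the eye stream (the highest rate), so no eye-event
timing is degraded; body signals are upsampled to it. Quaternions are
interpolated by slerp (hemisphere-aligned so the short arc is taken), yaws
linearly after unwrapping across ±180°, and eye vectors linearly with
renormalization. Edges clamp to the nearest sample, gaps larger than
100 ms (configurable) are an error naming their location, and
synchronizing twice is a no-op. Trial time zero is the first sample after
the alignment fixation that starts each trial, so all trials begin
centred at (0, 0).

# Fixations and saccades on the sphere

Detection is dispersion-threshold (I-DT) with the study's parameters:
dispersion 3°, minimum duration 80 ms. The classic I-DT dispersion
(horizontal plus vertical extent) is planar and distorts near the poles,
so dispersion is defined here as the **maximum pairwise orthodromic
distance** within the window, maintained incrementally (adding a sample
can only create new pairs involving it) and therefore exact. Windowing is
greedy left-to-right: the window grows until a sample violates the
threshold, is emitted as a fixation if it lasted at least 80 ms, and
scanning restarts at the violating sample — ties therefore resolve toward
the longer, earlier-starting fixation. Fixation centroids are renormalized
vector means, immune to longitude wraparound. Samples flagged invalid
(blinks, dropouts) split windows; nothing is interpolated across them.

Saccades are defined by successive fixation pairs: amplitude is the
orthodromic distance between centroids, duration the inter-fixation gap,
and candidates with gaps above 300 ms are ignored (such gaps are blinks or
tracking loss, not single gaze shifts). Detection runs on eyes-in-space:
the analyses are in world coordinates throughout.

# Exploration metrics

Total distance is the sum of saccade amplitudes per trial. Coverage is the
area of the union of spherical caps of radius θ = 3° (the dispersion
radius) around the fixation centroids, as a percentage of the sphere. A
single cap covers 50(1 − cos θ)% — 0.06852% at 3° — but overlapping caps
must not be double-counted, so the union is evaluated on a
**Fibonacci-lattice** grid (500,000 cells by default, ~0.0002% of the
sphere each): a cell counts as covered when its centre lies within θ of
any centroid. The lattice is equal-area by construction, so no pole
pathology arises; the estimator agrees with the analytic single-cap value
to ~0.1% relative error at the default resolution and with a 10⁶-point
Monte-Carlo union oracle within three standard errors (both asserted in
the test suite). Coverage uses fixation centroids, not raw samples,
because exploration is defined by what was fixated.

# Frame distributions, spreads, and biases

`frame_points()` exposes the nested hierarchy: eyes-in-space,
head-in-space, torso-in-space, torso-relative-chair (swivel only),
head-relative-torso, and eyes-in-head, with all angular differences
wrapped to [−180, 180). Spreads are **linear** (non-circular) standard
deviations of longitude and latitude, computed per subject after pooling
that subject's trials, then averaged over subjects — the same
subject-averages convention the repeated-measures tests use. The linear SD
is well defined here because trials start centred and observed spreads
(≤ 90°) are far from wrap saturation; for distributions approaching
uniformity on the circle it would be misleading, which is a documented
limitation rather than a supported regime. Sample SD (ddof = 1) is used
throughout at the subject level.

Equator biases are one-sample t-tests of subject-mean latitudes against 0
with Cohen's d = mean/SD (so d = t/√n exactly). The head-direction split
assigns eyes-in-head samples by the sign of the smoothed head yaw velocity
(100 ms boxcar, 5°/s dead band — the source analyses state no threshold,
so both are explicit configuration). Bimodality of a longitude
distribution is read from a kernel density estimate: the highest local
maximum on each side of the meridian (beyond a ±5° central exclusion)
qualifies as a side peak, and the distribution is flagged bimodal when
both side peaks reach at least 20% of the global density maximum — tail
ripples of a unimodal distribution therefore do not fire.

# Coordination dynamics

Eyes-in-head **eccentricity** is the angular offset of the eye from the
head's forward axis; it depends only on the eye-in-head vector and is thus
invariant to scene rotation. Profiles time-locked to saccade starts use a
[−400, +200] ms window in 4 ms bins (the 250 Hz timebase); events whose
window exceeds the trial are skipped and counted. The reported minimum is
the minimum of the **event-averaged** curve at or before onset — not the
average of per-event minima — and the 95% band is the between-event
standard error of the mean. Pooling across trials is event-level, so every
saccade weighs equally within a condition.

Rotation onsets use a speed threshold of 10°/s with 5°/s hysteresis, a
50 ms boxcar on the speed, and a 5° minimum accumulated movement — all
configuration-exposed, since the source analyses do not state their onset
criterion. Each torso onset is paired with the nearest
preceding-or-concurrent head onset within 500 ms; orphans on either side
are dropped, which keeps missed detections from biasing the delay.

# Group statistics

The unit of analysis is the subject × posture × stimulus cell mean.
`rm_anova()` runs fully within-subjects ANOVAs (one or two factors)
through `car::Anova()` on a multivariate fit; Mauchly's test gates the
Greenhouse–Geisser correction at α = .05 (both corrected and raw p-values
are reported, and corrected degrees of freedom are non-integer by
construction). Generalized eta-squared treats all factors as manipulated:
SS_effect / (SS_effect + all error SS including the between-subject SS).
Post-hocs are paired t-tests with Bonferroni multiplication capped at 1.
A zero-variance dependent variable is a structured error rather than a
silent F = 0.

# The synthetic generator

The generator emulates the movement structure the analyses assume, not
image content: no saliency, no pictures, only the second-order spatial and
temporal structure of posture-conditioned exploration.

**Trial plan.** Each 10 s trial is a stylized scan: an initial centred
dwell (0.4 s), then four sweep bouts separated by lulls. During a bout the
gaze target advances along a bounded out-and-back longitude path
(0 → +R → −R, direction randomized per trial) in saccade steps; each lull
is a micro-exploration cluster (0.55 s of targets laid out on a 3.8°
ladder around the current position, so the fixations stay distinct but
their 3° caps overlap, emulating local re-inspection) followed by a quiet
dwell (0.55 s). Fixation durations are gamma-distributed; their generative
means (151–157 ms) sit below the detected durations because saccade
transitions and dispersion-window merging lengthen detected fixations.
Fixation-target latitudes follow a slowly mixing AR(1) with the
condition's latitude spread.

**Kinematic chain.** The eyes jump to each target at the saccade; the head
relaxes exponentially toward the *current* target with a per-posture time
constant τ, so eyes-in-head eccentricity decays during each fixation and
jumps at each saccade — the sawtooth the locked profiles measure. During
quiet dwells the head drive ramps to zero within 0.35 s: real heads park
during stable fixation instead of creeping indefinitely, and this is also
what lets effector speeds fall below the onset detector's hysteresis
between movement bouts. The head target is capped at the neck range
(±80°) relative to the current torso, so in the sit posture — where the
torso barely moves — large gaze excursions are carried by sustained
eyes-in-head offsets (the compensatory pattern the posture comparison is
about) and head-relative-torso piles up near ±70–80°. The torso moves in
delayed constant-speed bursts toward a scaled copy of the sweep, starting
one configured delay after the head's bout onset; in the swivel posture
the chair carries the complementary share of torso-in-space rotation so
the torso-relative-chair spread stays near its configured 19.4°.

**Calibration is solved, not painted on.** Three quantities are solved
from the configuration rather than set by hand:

* the sweep amplitude R, from the requirement that the pooled fixation
  longitude SD equal the profile's spread (the schedule's
  position-weighted second moment has a closed form in R);
* the head time constant τ, by root-finding on a small fixed-seed ensemble
  of schedule realisations pushed through the *actual* detection and
  locking pipeline, so the configured eccentricity minimum emerges at
  fixation end rather than being inserted;
* the torso burst speed, matched to the head's instantaneous catch-up
  speed at a bout start, so threshold-crossing onset detection sees the
  same rise on both effectors and recovers the configured delay without
  bias (verified to within ±5 ms over hundreds of trials in the suite).

τ is solved once per posture and shared by that posture's subjects;
subject-level realism comes from 10% lognormal jitter on spreads and ±2°
uniform jitter on biases, which is what gives the repeated-measures
ANOVAs realistic between-subject variance. The within/between variance
decomposition of the original data is unreported, so these jitter
magnitudes are the package's calibration choice.

**Vertical biases.** The three reported vertical statistics — head
elevation ≈ +15°, eyes-in-head depression ≈ −10°, and gaze concentrated on
the equator — cannot all hold at once, because to first order gaze
latitude is their sum (+5°, not 0). The generator enforces the two that
the recovery analyses measure directly: the printed eyes-in-head biases
(−10.7/−9.9/−10.2°) are applied, gaze is equator-centred by construction,
and head elevation emerges as their negation (≈ +10°). The profile field
`head_lat_bias` retains the reported ≈ +15° values as reference metadata
only. Latitude dynamics beyond this static bias plus AR scatter (e.g.
pitch kinematics) are not modelled.

**Noise.** Measurement noise defaults follow the hardware characteristics
the apparatus description reports: 0.2° eye-tracker accuracy (white),
0.05° headset orientation, and 1.5° RMS on the torso and chair trackers.
The tracker error is modelled as slow drift (4 s correlation time) rather
than white noise: per-sample white error of that magnitude would imply
physically absurd instantaneous angular speeds and no orientation tracker
behaves that way.

**What passing tests do and do not show.** The recovery suite shows the
pipeline is unbiased and correctly plumbed for data with this nested
structure at study size (27 subjects × 3 postures × 30 trials). It does
not validate the generator as a model of human scanpaths: real gaze is
image-driven, revisits salient objects, has main-sequence kinematics and
smooth pursuit, none of which are modelled. Plausibility bands (fixation
counts 40–55 per trial, durations 150–250 ms, coverage ≈ 1.5–2.5%) keep
the synthetic trials in the study's neighbourhood; they are calibration
checks, not claims about human behaviour.

# Numerical choices and degenerate inputs

Unit-norm tolerances are 10⁻³ on ingestion (measurement-scale) and 10⁻⁹
internally. The dispersion check compares dot products against cos(3°)
rather than computing angles per pair. An empty gaze stream yields an
empty fixation table, not an error; fewer than two fixations yield no
saccades; a window with zero locked events yields an explicitly empty
profile, never fabricated bins. Zero-variance inputs to the t-based tests
are flagged. A profile with all spreads and biases zero generates
perfectly static streams at (0, 0), which pins the whole chain's origin.

# Problem sizes used by the tests

The acceptance suite runs one full-size study (27 × 3 × 30 = 2,430 trials,
about two minutes) for parameter recovery and the structural analyses, and
twenty replicates at 27 subjects × 4 trials per posture for the
spread-ordering property; module tests use handfuls of trials. The
`analysis/` scripts default to a 10-subject × 6-trial demonstration study
so the end-to-end chain (simulate → store → ingest → events →
distributions → coordination → inference) runs in a few minutes; pass
`--subjects 27 --trials 30` to `analysis/01_simulate.R` for the full
design.

# Known limitations

* Linear longitude SDs saturate for near-uniform circular spreads.
* The generator's sweep-lull structure is stylized; only its second-order
  statistics are calibrated.
* Latitude kinematics are static bias plus AR scatter.
* The onset detector is a stand-in for an unreported criterion; its
  parameters are exposed and its recovery verified only under the
  generator's movement structure.
* Coverage is fixation-based; time-resolved or sample-based coverage is
  out of scope.
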