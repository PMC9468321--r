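---
title: "Quantifying open-suturing skill from multimodal simulator streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying open-suturing skill from multimodal simulator streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sutureskill)
```

## The measurement problem

Bench-top suturing simulators instrument a radial suturing task: a clock-face
membrane with a circular "incision" and twelve needle-entry marks on radial
lines 30° apart, sutured continuously counter-clockwise starting at the
10 o'clock position, at two membrane depths ("surface" and recessed "depth",
emulating suturing inside a body cavity). Four synchronized data streams are
logged while a subject sutures:

* a 6-axis force/torque sensor under the membrane (1 kHz), with +z pointing
  upward out of the membrane;
* an inertial sensor on the dorsum of the dominant hand giving wrist yaw,
  pitch and roll (200 Hz, degrees);
* a capacitive touch channel that is high while the subject contacts the
  platform walls;
* a vision system under the membrane that yields, per stitch, the needle
  entry time, needle-tip exit time, complete pull-out time, and the entry and
  exit points in image coordinates.

`sutureskill` turns these streams into per-stitch skill metrics and an
attending-versus-resident group comparison. Event *detection* is out of
scope: the package trusts the per-stitch annotations, because every metric is
defined purely in terms of the annotated event times and points.

## Segmentation

*Active suturing time* for a stitch runs from needle entry to complete
needle removal; *idle time* runs from there to the next stitch's entry. All
intervals are half-open (`[start, end)`), so consecutive cycles partition the
sample grid with no double counting. A descriptive three-segment phase
labeling (entry+driving, exit, pull-out) is provided; with only three stored
event times the four conceptual phases cannot all be reconstructed, so the
boundary between exit and pull-out falls back to the midpoint of
`[t_exit, t_pullout)` unless a thread-entry time is annotated. No metric
depends on phase labels.

## Preconditioning

Force/torque channels are low-pass filtered before metric extraction; motion
and touch are used raw. The filter contract is a 10th-order Butterworth
low-pass at 50 Hz applied forward and backward (zero net phase). Two readings
of "10th-order zero-phase" are possible; we design a 10th-order filter and
run it twice, so the effective magnitude response is the square of a
10th-order Butterworth. The alternative (5th order per pass) is rejected
because the stated order names the designed filter, not the cascade.

Numerics: the design is realized as a cascade of second-order sections
obtained by bilinear transform of the analytic Butterworth prototype poles,
each section normalized to exactly unit DC gain. The expanded 11-coefficient
transfer function of a 10th-order design at this cutoff loses about 1e-8 of
DC accuracy in double precision; the cascade keeps the filter's DC error at
machine precision, which the package's 1e-9 DC contract requires. Edges are
handled by odd (point-symmetric) reflection padding of length 3× the filter
order with steady-state initial conditions, so constants pass through
exactly. The edge-handling convention is ours; the measurement chain does
not prescribe one.

## Metric functionals

For a windowed channel $X(t)$ over an active suturing time:

* $\mathrm{PEAK}_+(X) = \max_t X(t)$ and $\mathrm{PEAK}_-(X) = -\min_t X(t)$.
  The negated minimum is applied literally, so $\mathrm{PEAK}_-$ of an
  all-positive signal is negative; we do not clamp at zero, and the tests pin
  this edge case.
* $\mathrm{PP}(X) = \mathrm{PEAK}_+ + \mathrm{PEAK}_-$, the peak-to-peak
  amplitude.
* $\mathrm{INTABS}(X) = \int |X|\,dt$, impulse-like for a force.
* $\mathrm{DER}(X) = \int (dX/dt)^2\,dt$, a consistency/smoothness
  surrogate.

The integrals are written as continuous functionals without a prescribed
discretization; we use trapezoidal quadrature on the sample grid and central
differences (one-sided at window edges) — both second-order accurate and
standard. All five functionals are applied to the six force/torque channels
(30 metrics per stitch); the three peak functionals to the stitch-frame
forces (6); peak-to-peak to the three wrist angles (3); plus the touch count
(1): 40 metrics, hence 480 records for a 12-stitch session.

### Stitch-frame forces

The force sensor's axes are fixed while stitch directions rotate around the
clock face, so horizontal forces are re-expressed per stitch. With
calibration unit vectors $\vec e_x, \vec e_y$ (sensor axes in the vision
frame) and stitch unit vectors $\vec e_t$ (entry→exit) and $\vec e_o$
($\vec e_t$ rotated +90° counter-clockwise),

$$[F_o; F_t] = [\vec e_o\ \vec e_t]^{-1} [\vec e_x\ \vec e_y] [F_x; F_y]$$

per sample. For orthonormal bases this is a rotation and conserves the
per-sample norm; the implementation accepts any invertible calibration. The
sign of $\vec e_o$ is a convention (the geometry fixes it only up to
reflection), so $\mathrm{PEAK}_\pm(F_o)$ are side-sensitive while
$\mathrm{PP}(F_o)$ is not — a caveat worth remembering when interpreting
one-sided orthogonal-force metrics. Torques are not decomposed; the
stitch-frame transform is applied to forces only.

### Touch counts

A touch is a rising edge of the binary contact channel. Counts are
attributed per suture cycle — from one active start to the next active start
(stream end for the last stitch) — so contacts while preparing the next
stitch count toward the stitch just completed. Whether the count should
instead cover active time only is ambiguous in the protocol's wording; the
per-cycle reading is the default and `touch_scope = "active"` switches to
the alternative.

## Statistical protocol

Per metric and depth condition, per-stitch values are pooled across subjects
within each experience group — *each stitch is one trial* — and the groups
are compared with a two-sided Wilcoxon rank-sum test at α = 0.05. A
Lilliefors normality screen (Dallal–Wilkinson approximation) is computed per
metric, depth and group and reported, but never gates the rank test; it
documents why a rank test is used rather than selecting the test per cell.
Surface and depth are analyzed separately. Raw p-values are the default (no
multiplicity correction, matching the protocol being reproduced);
Benjamini–Hochberg is available behind `adjust = "BH"`.

The rank-sum implementation switches methods explicitly: the exact null
distribution when the smaller group has ≤ 10 observations and the pooled
sample is tie-free, otherwise the normal approximation with mid-ranks,
tie-corrected variance and continuity correction. The method used is
recorded in every output row. Quantiles everywhere (comparison tables,
box-plot summaries) use the linear-interpolation (type-7) convention, and
box-plot whiskers extend to the most extreme data points, outliers included.

Pooling stitches across subjects ignores within-subject correlation. That is
a deliberate fidelity choice — it reproduces the protocol under study — and
a known statistical limitation: the effective sample size is overstated when
subjects differ systematically, and no mixed-model substitute is offered.

## The synthetic bench

No public recordings of this instrument exist, so the package ships a
generator that emulates the study conditions and provides exact per-stitch
ground truth. Design choices:

* **Force shape.** Phase-structured raised-cosine (sin²) bumps: a downward
  z-bump while puncturing (first 30% of active time), an upward z-bump while
  pulling out (last 35%), orthogonal/tangential bumps in the stitch frame
  during the driving window (25–70%), mapped to sensor x/y through the
  inverse calibration. The metrics consume only extrema, integrals and
  derivatives, so smooth compact bumps with controllable amplitude make
  ground truth exact without a biomechanical needle–membrane model.
* **Bipolar z-torque.** The z-torque carries a positive bump during driving
  and an opposite-signed bump (independently drawn amplitude, same
  distribution) during pull-out — physically, the untwisting reaction while
  the thread is drawn. A strictly one-sided torque would make its
  negative-peak metric pure noise and thus uninformative by construction.
* **Event-grid snapping.** Event times are snapped to a 10 ms grid (the
  common multiple of the 1 kHz/200 Hz/100 Hz sampling periods) and bump
  windows to odd sample counts, so each bump's peak lands exactly on a
  sample and noise-free recovery is exact to machine precision rather than
  limited to ~2.5e-6 by grid misalignment.
* **Touches.** Poisson-distributed counts per cycle realized as 50 ms
  contact pulses placed uniformly, non-overlapping by rejection; rising-edge
  counting needs finite-width pulses.
* **Calibration.** Default is a 20° rotation, never the identity, so any
  code path that silently assumed identity calibration would fail the
  recovery tests.
* **Noise.** Additive white Gaussian per channel. No drift, 1/f or
  quantization components: there is no evidence to parameterize them, and
  the tests therefore say nothing about robustness to such structure.

### Default parameter values

Group differences enter through per-stitch amplitude draws (truncated-normal
at zero). Attending-to-resident ratios are 0.6 for puncture/pull-out force,
orthogonal force, z-torque, yaw/roll sweep and touch rate, and 1.3 for
tangential force; pitch sweep, durations and noise are shared. Magnitudes
are not published for this instrument, so the resident means are set to
plausible open-suturing scales — 3 N puncture, 2 N pull-out, 1 N horizontal,
0.05 N·m z-torque, 40°/30°/60° yaw/pitch/roll sweep, 1 contact per cycle,
5 s active and 3 s idle time — with sensor-grade noise floors (0.05 N force,
5e-4 N·m torque, 0.5° orientation). Two of these choices are load-bearing
and deliberate:

* The resident orthogonal and tangential means are **equal** (1 N each).
  Sensor x/y channels see the mixture `A_o·cosφ + A_t·sinφ` across stitch
  angles φ, and with equal means the 0.6/1.3 group ratios nearly cancel in
  that mixture (√(0.36+1.69) ≈ 1.43 vs √2 ≈ 1.41) while remaining fully
  visible in the stitch frame. This emulates the construct-validity pattern
  the instrument is designed to show: stitch-frame forces discriminate,
  raw x/y forces do not.
* The torque noise floor is set independently of the force noise. A torque
  noise scaled naively from the force channel would dominate the
  differentiated-signal (consistency) metric for z-torque and bury its group
  effect in integrated noise.

## What the tests do and do not show

The validation suite demonstrates: exact agreement of the functionals with
brute-force oracles; the filter's DC/passband/stopband/zero-lag contract;
norm conservation and exact injection recovery through the decomposition at
all twelve clock positions; exact segmentation and count recovery; type-I
calibration of the rank test (2,000 null replicates at n = 200 per group)
and of the full pipeline under a global null; and reproducible separation of
the designed group effects in 20 replicate cohorts of 5 attendings and 7
residents at both depths (60 vs 84 trials per cell). Problem sizes in the
routine tests use shortened sessions (1.5 s active, 0.8 s idle) where only
pipeline mechanics are at stake, and the full default conditions where
cohort-level claims are made.

Passing these tests shows the pipeline is correct and the protocol behaves
as designed *on data matching the generator's assumptions*. It does not show
that real suturing data are bump-shaped, noise-white, or free of
within-subject correlation, and it cannot reproduce p-values from restricted
human-subject recordings.

## Known limitations

* Stitch pooling overstates the effective sample size (above).
* The Lilliefors wrapper requires n ≥ 5 (the underlying approximation is not
  defined below that); the pipeline never calls it with fewer than 60 values.
* Phase labels are descriptive; the exit/pull-out boundary is a midpoint
  fallback when no thread-entry time is annotated.
* The reader rejects gapped or jittered time grids rather than imputing;
  streams must be uniformly sampled.
* Units are fixed (N, N·m, degrees, seconds) and validated; there is no
  conversion layer.
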