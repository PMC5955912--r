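---
title: "Models and methods of the opto-locomotor reflex pipeline"
author: "olrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the opto-locomotor reflex pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olrkit)
```

## The assay and its readout

A head-fixed mouse runs on a Styrofoam ball floating on pressurised air at
the centre of a 112-cm dome. Random dot patterns are projected on the inside
of the dome over a window spanning 220° of azimuth and −10° to +80° of
elevation. Each trial starts with 1 or 2 s of static dots (interleaved, so
motion onset cannot be anticipated), then the pattern drifts left or right
for 2 s, then stands still for a final second. The mouse reflexively turns
with the pattern; because the head is fixed, the turning is transferred to
the ball, whose yaw is sampled at 60 Hz. The opto-locomotor reflex (OLR) of
a trial is a single number: the mean baseline-corrected yaw between 1 and
2 s after motion onset, in deg/s, with the sign convention that positive
means turning with the stimulus.

## Stimulus geometry

**Isotropic dot sampling.** Azimuths are uniform over the window; elevations
are `asin(U)` in degrees with `U` uniform on `[sin(ele_min), sin(ele_max)]`.
The arcsine transform makes the density uniform per unit solid angle —
without it dots would crowd towards the zenith, where horizontal circles of
the dome shrink.

**Coverage rule.** The number of dots is inversely proportional to the
per-dot solid angle so that 27% of the window stays covered at every dot
size, keeping mean luminance constant. A dot of angular radius $r$ is
treated as a spherical cap with solid angle $2\pi(1-\cos r)$ rather than a
planar disc of $\pi r^2$; at the radii used (0.6°–3.7°) the difference is
below 0.1%, but the assay's geometry is spherical throughout so the cap is
the natural primitive. With the default window (solid angle 4.448 sr) a
1.4° radius gives 640 dots.

**Motion and wrap-around.** Motion is a pure yaw rotation: azimuths advance
by `speed/60` degrees per video frame; elevations never change. Dots leaving
the ±110° window re-enter at the opposite edge. The wrap rule is our choice
(what happens to exiting dots is otherwise unspecified); it is the only
simple rule that keeps dot count, density and hence coverage constant during
motion, consistent with the constant-coverage design.

**Projection lookup table.** The dome mapping is calibrated by measuring the
azimuth and elevation of 200 dots projected in a 20 × 10 raster evenly
spaced in projector pixels. We store that grid once and, for a query
`(azi, ele)`, locate the grid cell whose measured angle quadrilateral
contains it, invert the cell's bilinear angle map by Newton iteration, and
read off the pixel coordinates at the recovered cell-local position. This
per-cell inversion is exact at every node and exact everywhere when the
calibration is affine; on a smooth synthetic dome model the round-trip
angular error stays below 0.5° (tested). Queries outside the calibrated
hull are errors, not extrapolations.

**Component dots.** Each displayed "dot" is a cluster of 21 partially
overlapping component dots, so that pushing every component through the
lookup table individually keeps the cluster circular from the mouse's
viewpoint even where the projector hits the dome obliquely. Only the count
(21) and the three-concentric-circles structure are fixed by the assay; we
use rings of 6, 7 and 8 components at radii $r/3$, $2r/3$ and $0.98r$,
evenly spaced in angle starting at 0°. These sum to exactly 21, are
deterministic, and leave no gaps (the inner ring's overlap covers the
centre, so no separate centre component is used).

## Experiment design

Three experiments share a factorial skeleton of speed × direction ×
static-phase duration:

* **speed**: 9 speeds (0–72 deg/s in steps of 9) × 2 × 2 = 36 conditions,
  contrast 0.68, radius 1.4°; 10 repeats per session × 7 sessions.
* **contrast**: 5 speeds (0, 18, 36, 54, 72) × 2 × 2 × 5 contrasts
  (0.09–0.95) = 100 conditions; 5 repeats × 14 sessions.
* **dotsize**: as contrast but with 5 radii (0.6°–3.7°) at contrast 0.68.

Every plan repeats each condition 70 times. The zero-speed condition is part
of every grid — it supplies the static-stimulus reference that is subtracted
from all motion conditions — and both direction labels are kept for it,
preserving the factorial structure and the condition counts. Sessions use a
randomly interleaved block design, implemented as consecutive independent
permutations of the full condition set; we impose no constraint across block
boundaries, the simplest reading consistent with exact per-session counts.

Contrast conditions are parameterised by the projected dot luminance (0.11
to 3.98 cd/m² on a 0.09 cd/m² background). The conventional two-decimal
contrast labels are attached as metadata rather than recomputed, because
recomputing Michelson contrast from the two-decimal luminances disagrees
with the labels in the second decimal (e.g. 0.5 cd/m² gives 0.695, label
0.68); the labels were evidently derived from unrounded photometer readings.
`michelson_contrast()` is provided and its output matches every label at the
labels' printed precision.

## Reflex extraction

The preprocessing chain is deliberately minimal and linear:

1. **Boxcar smoothing**, 100 ms = exactly 6 samples at 60 Hz. The filter
   phase is a free choice; we centre the window (3 samples left, 2 right)
   and shrink it at trace edges. A centred window does not bias the latency
   of the analysis window, which a causal filter would.
2. **Baseline subtraction**: the mean of the 30 samples in the final 500 ms
   before motion onset is subtracted from the whole trace. This removes the
   per-trial forward-running yaw offset; smoothing runs first, baseline
   second (the order changes baselines slightly, so it is fixed).
3. **OLR window**: the half-open window `[t0+1 s, t0+2 s)`, exactly 60
   samples, so adjacent windows would never double-count a boundary sample.
4. **Zero-speed correction and folding**: per mouse (and per level of the
   second factor), `OLR(s) = ((R(s) − Z) + (−1)(L(s) − Z)) / 2`. The
   zero-speed trials of both direction labels are pooled into the single
   reference `Z`; as a consequence the corrected zero-speed response is
   identically zero — exactly, not just in expectation — and zero-speed
   conditions are excluded from all fits and gain curves.
5. **Across-mouse normalization**: each mouse's OLR-vs-condition vector is
   z-scored and rescaled, `norm = z · sd_pop + mean_pop`.

For the normalization's population constants we use the across-mouse
*means of the per-mouse curve means and SDs* (with divide-by-`n`
denominators), not the moments of all values pooled. The two readings differ
when mice differ in amplitude: pooled moments fold the between-mouse
amplitude variance into `sd_pop`, which inflates the modulation of every
normalized curve by `sqrt(1 + var(g)·E[f²]/var(f))` for multiplicative gain
spread `g` — a ~29% inflation at a threefold spread, i.e. a biased estimate
of the population tuning amplitude. The per-mouse-average reading equalizes
every mouse's curve exactly (identical mean and SD afterwards), preserves
the pooled mean exactly, and leaves the population-mean curve unbiased; this
matches the normalization's purpose of preventing strong responders from
dominating the condition means. The pooled SD is preserved only for
homogeneous cohorts, which the tests assert in exactly that form.

Condition summaries treat the mouse as the unit of replication (mean and
SEM over the per-mouse values) and flag conditions whose two-sided
one-sample t-test against zero has p > 0.05, mirroring the open plot
markers used for such conditions. Whether those t-tests should see raw or
normalized OLRs is not fixed by the assay; summaries accept either column
and default to the normalized one, consistent with every other statistic in
the pipeline being computed on normalized values.

## Weighted fits, model selection, peaks

Condition means `y` with standard errors `se` are fitted by linear least
squares with residuals weighted linearly by `1/se` (objective
`Σ((y−ŷ)/se)²`), using raw-polynomial design matrices and `lm.wfit`. The
weighted R² is `1 − RSS_w/TSS_w` with `TSS_w` about the weighted mean.
polyMN surfaces use the term rule `i ≤ M`, `j ≤ N`, `i + j ≤ max(M, N)`,
the unique simple rule that reproduces the assay's parameter counts
(poly22 = 6, poly23 = poly32 = 9, poly33 = 10).

Nested models are compared with
`F = ((RSS_s − RSS_l)/Δp) / (RSS_l/(n − p_l))` on `(Δp, n − p_l)` degrees
of freedom; both RSS terms are weighted, consistently with the fits being
weighted (whether the original analysis used weighted or raw RSS in its
F-tests is not stated; weighted is the internally consistent choice). With
8 speed conditions this gives the familiar df pairs (1,5) for line vs
quadratic and (1,4) for quadratic vs cubic; with 20 surface points, (3,11)
for poly22 vs poly23. Model order is selected stepwise-up: accept the larger
model while its F-test has p < 0.05, stop at the first rejection. The
F-test's empirical type-I error is verified by simulation to sit within
[0.03, 0.07] at α = 0.05 over 2000 null replicates.

**Peak finding.** 1D model maxima are found analytically (real roots of the
derivative plus the domain endpoints); surface maxima by a 201×201 grid scan
refined with bounded quasi-Newton steps. The search domain is the closed
tested range of each factor; maxima attained on the boundary (including the
degenerate upward-curved quadratic) are flagged rather than silently
reported as tuning optima. The implementation is cross-checked against
dense-grid argmax search on random surfaces.

**Bootstrap.** Peak uncertainty comes from refitting the model to 200
resamples (with replacement) of the individual mouse × condition points —
the point, not the mouse, is the resampling unit, matching the "48 data
points (6 mice × 8 speeds)" bookkeeping of the assay. Each resample is
re-aggregated into condition means and SEMs before refitting, so the
weights are resampled along with the data. A resample missing a condition
entirely cannot be fitted and is redrawn (counted and reported); a condition
drawn with a single point, whose SEM is undefined, or with identical points
(zero SEM) receives the smallest positive SEM of that resample as a floor —
equal weights if none exists. Peak dispersion is reported both as the
bootstrap SD and as 2.5/97.5 percentile intervals; the exact construction of
the original shaded bands is not stated, and pointwise percentiles are the
standard default. For surfaces the 95% confidence region of the peak
location is the normal-theory ellipse of the bootstrap location covariance
(`qchisq(0.95, 2)` scaling), since the construction of the original dashed
ellipses is likewise unstated.

Gain analyses (OLR divided by the evoking speed, defined only for moving
stimuli) repeat the identical machinery on the per-condition gain means and
their own SEMs.

## The synthetic cohort generator

The deposited behavioural data are not needed for any test: the generator
produces every trial of an experiment with known ground truth, and its
defaults are the assay's study conditions (6 mice, the condition grids
above, 70 repeats per condition).

* **Tuning truth**: a concave quadratic in speed, zero at rest, with its
  maximum at `peak_speed = 57.2` deg/s and `peak_olr = 35` deg/s, times
  saturating (Naka–Rushton-style) factors in contrast and dot radius that
  equal 1 at the reference condition (contrast 0.68, radius 1.4°). In the
  speed experiment the true peak is therefore exactly (57.2, 35.0).
* **Response dynamics**: a first-order step response — latency 0.1 s, time
  constant 0.1 s, exponential decay after motion offset. The measured traces
  rise smoothly to a plateau well within 1 s but their exact dynamics are
  uncharacterized, so these are stand-ins; they are chosen fast enough that
  the 1–2 s window reads the plateau to within 0.01%, i.e. the window-
  closure error is negligible against the pipeline's ~0.1% estimation
  precision, so recovery tests measure the pipeline and not the generator.
* **Heterogeneity**: per-mouse gain multipliers are log-spaced over a
  threefold range (the spread reported between the weakest and strongest
  responder) and rescaled to mean 1, so the population-mean curve equals
  the truth. An optional lognormal jitter of each mouse's preferred speed
  exists but defaults to off: the point-level bootstrap treats points as
  exchangeable and does not model mouse-correlated shape deviations, so
  with shape heterogeneity switched on the reported intervals understate
  the estimator's true sampling error (they are then intervals for the
  cohort's mean curve, not the population truth).
* **Noise**: white Gaussian sample noise (SD 10 deg/s) plus a per-trial
  constant yaw offset (SD 5 deg/s). This is the simplest model under which
  both the boxcar and the baseline subtraction are consequential. Real
  running noise is autocorrelated and non-stationary; none of that is
  emulated, so passing recovery tests demonstrate correctness of the
  pipeline's arithmetic and calibration of its intervals under the stated
  model, not robustness to real-world noise structure.

One consequence of the quadratic-through-zero tuning truth: its gain curve
`f(v)/v` decreases monotonically in speed, so the simulated gain optimum
always sits at the lowest tested speed and is flagged as a boundary maximum.
Real gain curves peak at intermediate speeds because measured OLRs rise
slower than linearly at low speeds; reproducing that would need a different
truth model and is not required for the recovery tests, which target the
OLR peak.

## Consistency splits

`session_split_analysis()` re-runs the entire pipeline on two halves of a
dataset: either the first versus second half of every session's trial
sequence, or each mouse's sessions before versus from the middle session
index onward. The halves' bootstrap peak intervals are compared per axis,
and the late/early amplitude ratio over conditions is reported. On a
stationary simulated cohort the halves are statistically indistinguishable;
on a cohort whose later sessions are twice as strong, the late curve is
about twice the early one while the peak-speed intervals still overlap —
the reflex's preferred speed is a more stable quantity than its amplitude.

## Problem sizes and numerical choices

The test suite verifies oracle equivalence (normal-equation solver at 1e-8
relative; direct-convolution and window-mean oracles exactly), F-test
calibration over 2000 null simulations, model selection over 200
simulations, and end-to-end peak recovery over 50 replicate full assay-scale
experiments with 200 bootstrap resamples each — sizes chosen so each
statistical property is measured with a few-percent standard error while the
whole suite completes in about a minute. All randomness is seeded; sampling
utilities accept explicit seeds and restore the caller's RNG state.

Known limitations: the CSV interchange stores doubles at 17 significant
digits (round trips are exact only to that representation); the LUT refuses
queries outside the calibrated hull rather than extrapolating; and the
bootstrap's exchangeability assumption above is the main caveat when mice
differ in tuning shape rather than amplitude.
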