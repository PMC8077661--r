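---
title: "Methods: a virtual intensity-polarization optomotor drum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a virtual intensity-polarization optomotor drum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polardrum)
```

## The experimental setting this package models

Many aquatic crustaceans can detect the linear polarization of light, but
whether they use it for *gaze stabilization* — the reflexive eye (OKR) and
body (OMR) rotations that follow a moving visual surround — is a separate
question from whether they can see it at all. The behavioural apparatus for
asking that question is a *virtual optomotor drum*: four flat
intensity-polarization screens arranged as a square arena around the
animal, each screen driving an intensity image and a polarization image
independently. Rotating striped patterns rendered with perspective
correction create the illusion of a cylindrical drum; looming discs test
whether a channel that fails to drive stabilization can still drive an
escape response. This package re-implements the full computational chain —
stimulus synthesis, screen polarization model, response analysis, and
threshold estimation — and pairs every stage with a synthetic-data
generator so the whole pipeline can be validated closed-loop without
animals.

## Arena geometry and perspective correction

The arena is four planar walls of width 38.5 cm and height 30.0 cm meeting
at right angles; a central viewer sees each wall subtend exactly
$2\arctan\!\big(\tfrac{w/2}{w/2}\big) = 90^\circ$ horizontally. Vertically
the subtense depends on the eye height $z_e$ above the wall bottom:
$\arctan\!\frac{h - z_e}{d} + \arctan\!\frac{z_e}{d}$ with $d = w/2$. For a
mid-height eye this is $2\arctan(15/19.25) \approx 75.9^\circ$. Because the
animal's true eye height is never known precisely, `arena_geometry()`
exposes `viewer_eye_height` (default: mid-height) rather than hard-coding
a vertical subtense.

Conventions, fixed once so that drift direction and seam continuity are
well defined:

* azimuth 0 at the centre of panel 0, increasing counter-clockwise seen
  from above; elevation 0 at the viewer's eye height;
* pixels are 0-based with centres at half-integer physical offsets, so
  continuous pixel coordinates live on $[-0.5,\ \mathrm{size}-0.5]$;
* panels are ideal rectangles with zero-width seams (no bezel data is
  available for real hardware, and the virtual drum needs none).

`panel_pixel_to_direction()` casts the ray from the viewer through a pixel
centre; `direction_to_panel_pixel()` inverts it by plane intersection. The
pair is exact up to floating point, which the test suite checks by a
0.5-px round-trip bound over all four panels and by comparison against an
independent ray-casting oracle built from the panel corner coordinates.

## Stimuli

**Gratings** are square-wave stripe patterns defined *on the drum*, i.e.
as a function of azimuth with period $1/f$ degrees at spatial frequency
$f$ (cycles/deg). Sampling that function through the pixel-to-direction
map is what performs the perspective correction: the stripe width measured
through the inverse map is constant anywhere on a panel. The drum rotates
at 6 deg/s by default, the speed that reliably drives optomotor responses
in these species. Stripe drive values are the channel extremes scaled by
`contrast_level` about the grayscale midpoint 127 (the grey control
drive): $\mathrm{lo} = 127(1-c)$, $\mathrm{hi} = 127 + 128c$, so full
contrast reaches the 0/255 extremes. A square wave (50% duty) rather than
a sinusoid matches the classic striped-drum stimulus.

**Looms** are discs whose angular diameter grows geometrically —
a constant size ratio per unit time, pinned to both endpoints:
$$\theta(t) = \theta_0 \left(\frac{\theta_{\max}}{\theta_0}\right)^{t/T},$$
reaching $\theta_{\max} = 34.5^\circ$ in $T = 5$ s. The onset size
$\theta_0$ is not a measured quantity; the default 0.5 deg is the smallest
plausibly visible onset and is configurable. A constant-approach-velocity
profile is the main alternative reading of "geometric expansion"; the
size-ratio form is adopted because it is the one pinned naturally to both
endpoints, and the profile function is isolated behind `loom_angle_at()`
if a different profile is ever needed.

**Rendering.** `render_frames()` evaluates the drum pattern on a
supersampled (2×2 per pixel, then mean) direction map, which anti-aliases
stripe and disc edges that cross pixels obliquely after perspective
mapping. Frame $i$ shows the pattern at $t = i/\mathrm{fps}$ (end of the
frame interval): this makes the final loom frame display exactly
$\theta_{\max}$, which is the quantity the verification round trip
measures on the last frame. The channel not carrying the stimulus is held
at the constant grey background drive. Rendering refuses spatial
frequencies with fewer than 2 px per half-period at the panel centre
(aliasing guard).

Two measurement utilities close the loop through the renderer itself:
`measure_loom_diameter()` sums per-pixel solid angles weighted by each
pixel's foreground fraction and converts the total to a spherical-cap
diameter; `measure_grating_drift()` fits the stripe fundamental's phase on
the inverse-mapped eye-level row of every frame and reports the slope of
phase against time. Both operate only on rendered pixels, so they verify
what an observer at the arena centre would actually see. At the default
192×148 px panels they recover the 34.5-deg final diameter to well within
one pixel's angular size (≈ 0.47 deg) and the 6 deg/s drift to better
than 0.1%.

## The screen polarization model

The polarization channel of each screen maps a grayscale drive (0–255)
onto an emitted light state described by intensity, degree of polarization
(DoP) and angle of polarization (AoP, 0–180 deg, 0 = horizontal). The
measured extremes of the real screens anchor the default calibration: one
end emits horizontally polarized light with DoP = 1, the other vertically
polarized light with DoP = 0.45, with emitted intensity constant across
drives — the defining feature of an independently driven
intensity/polarization display. Between the anchors the full calibration
curve lives in hardware-specific measurements, so `screen_calibration()`
defaults to a piecewise-linear DoP through a zero-DoP crossover at drive
127 and accepts a measured `(drive, dop, aop_deg)` table when one exists.

**Receptor model.** A two-channel polarization vision system with
orthogonal analysers (horizontal/vertical) and polarization sensitivity
$S_p = 10$. The quantum catch of a receptor with axis $\phi$ viewing a
state $(I, d, \theta)$ is the two-axis absorber
$$Q = S_p E_\parallel + E_\perp,\qquad
E_\parallel = I\left[\tfrac{1-d}{2} + d\cos^2(\theta-\phi)\right],$$
whose closed form
$Q = I\,\tfrac{S_p+1}{2}\left[1 + d\,\tfrac{S_p-1}{S_p+1}\cos 2(\theta-\phi)\right]$
is implemented and verified against the explicit decomposition to
$10^{-12}$ relative error on $10^4$ random states.

**Polarization distance.** Each state is reduced to the normalized
opponent signal $s = (Q_H - Q_V)/(Q_H + Q_V)$ and the contrast between
object and background is $PD = |s_{obj} - s_{bkg}|$. This
opponent-signal-difference form follows directly from the two-channel
opponent construction; it is zero exactly when the receptor pair cannot
distinguish the states, symmetric, and monotone in the AoP difference for
fully polarized equal-intensity pairs — all properties the suite checks.
No published numeric value exists for the H(1.0)/V(0.45) stripe pair this
apparatus uses, so verification is oracle- and property-based; alternative
distance definitions can be swapped behind the same interface. For
intensity stimuli the package uses Michelson contrast for gratings and the
Weber fraction for looms, the conventional pairing of contrast measures
with periodic versus object-on-background stimuli.

**Polarimetry.** Four-angle division-of-time polarimetry (0/45/90/135 deg)
is inverted by the standard Stokes estimators $S_0 = I_0 + I_{90}$,
$S_1 = I_0 - I_{90}$, $S_2 = I_{45} - I_{135}$, with DoP clipped to
$[0,1]$ and AoP mapped to $[0,180)$; pixels with $S_0 = 0$ are masked NA
rather than propagated. The synthetic forward model (Malus's law) is
inverted exactly on noiseless stacks.

## Response analysis

**Marker tracking.** Bright paint markers are detected per frame by
threshold → connected components (EBImage) → area filter →
intensity-weighted centroids, with identity maintained across frames by
nearest-neighbour linking under a maximum jump radius. The default
threshold is adaptive (mean + 4 sd of the frame) so blank or pure-noise
frames yield a flagged dropout rather than spurious blobs. Two tracked
markers are reduced to the orientation of the marker pair — invariant to
translation and to the unknown body centre; a single marker falls back to
its bearing from a fixed centre. Dropout gaps up to `gap_limit` frames
(default 5) are linearly interpolated and flagged.

**Nystagmus segmentation.** The trace velocity is smoothed over 0.2 s;
samples moving against the stimulus faster than `v_saccade_min`
(30 deg/s) are saccade candidates, merged into intervals and bounded by
`max_saccade_duration` (0.5 s). Each interval between saccades is
labelled by its regression slope: a slow phase if the slope matches the
stimulus direction with magnitude in `[v_min, v_slow_max]` (defaults
1 deg/s and twice the stimulus speed), quiescent otherwise. Labelling
whole inter-saccade intervals by their fitted slope, rather than
classifying noisy per-sample velocities, is what keeps slow phases
detectable at 1 deg of angle noise and tracking gains as low as 0.25.
Gain is the slow-phase slope divided by stimulus speed. None of these
thresholds is measurable from published material — responses in most
species were scored by eye — so all are config-exposed; the defaults
follow classic nystagmus-analysis practice. An optional consistency
filter demotes saccades with no adjacent slow phase, mirroring the known
false-positive source of isolated non-tracking eye movements (e.g. eye
cleaning).

**Scoring.** An OKR is positive when the slow-phase time fraction reaches
`f_min` (0.3) and at least `n_min` (2) resetting saccades occurred (closed
thresholds). An OMR follows the two-reversal confirmation rule for freely
walking animals: at least one full circuit (360 deg) in the stimulus
direction, a full circuit in the new direction after the first reversal,
and resumed following (default ≥ 90 deg) after the second. Response
records aggregate to per-group positive fractions with binomial counts and
across-individual mean ± s.e.m.

## Contrast staircase and CSF assembly

Per frequency and channel, the staircase starts at full contrast and
descends (default: halving) until the first non-eliciting level, then
bisects the bracket between the last eliciting and first non-eliciting
contrast until the bracket is narrower than `resolution` (default 0.01
Michelson, below the finest threshold of interest ~0.11); the threshold is
the bracket's responding bound. The trial count after the first
non-response is logarithmic in the resolution. Frequencies (0.02–0.2
cycles/deg) are tested independently in seeded random order with no
carry-over. An individual that fails to respond at full contrast is a
*non-responder* and is assigned the sentinel 1.2 — an impossible Michelson
contrast — so that it still contributes to the cohort average instead of
silently dropping out; cohort curves report mean ± s.e.m. per frequency
with the sentinel averaged in (s.e.m. is 0 for a single subject by
convention).

## What the synthetic data emulate — and what they do not

`synthetic_observer()` stands in for the animal: per channel, an
inverted-U threshold curve (log-parabola in log frequency — the standard
minimal CSF form) and a logistic psychometric function of log contrast.
Defaults are fixed once as the package's study conditions: peak threshold
0.11 Michelson at 0.07 cycles/deg (the most sensitive operating point
measured behaviourally in shore crabs), log-bandwidth 0.8 (keeps
edge-of-range thresholds attainable, as real animals responded across the
whole 0.02–0.2 range), slope 20 per log10 unit of contrast
(near-deterministic, consistent with all-or-none scored responses), and
guess = lapse = 0 (polarization gratings elicited no spontaneous false
positives after scoring). The polarization channel is blind (infinite
threshold) by default while `loom_response` stays on — the dissociation in
which polarization supports object-motion vision but not wide-field
stabilization.

`make_nystagmus_trace()` produces slow tracking at `gain × stim_speed`
with single-sample resetting saccades every 10 deg of excursion plus
Gaussian angle noise, returning ground-truth labels;
`make_marker_video()` renders Gaussian spots on a dark background with
optional occlusions and noise; `make_polarimetric_stack()` applies
Malus's law to ground-truth maps. Every generator is deterministic under
a fixed seed and emits its ground truth beside the data.

These generators validate the *pipeline*, not the biology: real eye
traces have variable saccade amplitudes, drifting baselines and
non-stationary gains; real marker videos have carapace texture, glare and
perspective foreshortening; real screens have spectral and angular
non-uniformities. A passing closed loop therefore demonstrates that the
analysis recovers known ground truth under idealized conditions, not that
it would be unbiased on any particular animal's data.

The closed-loop benchmark runs the default observer through the full
chain — observer → per-frequency staircases → cohort CSF — with a cohort
of 9 individuals (the typical cohort size in this paradigm) and compares
the assembled cohort-mean curve to the generating curve; it recovers the
inverted-U to within twice the bisection resolution in mean absolute
error. A single staircase against a stochastic observer is intrinsically
noisier (the bisection queries are coin flips near the p = 0.5 contrast),
which is exactly why cohort averaging is part of the design.

## Numerical choices and degenerate inputs

* Angles are degrees everywhere in external interfaces; AoP arithmetic is
  mod 180, azimuth mod 360; traces are unwrapped before analysis.
* `direction_to_panel_pixel()` absorbs ~1e-9-scale round-off at wall
  edges; directions above/below the walls return NA by contract.
* Both-zero radiances (Michelson), zero background (Weber), all-dropout
  videos, empty record sets, out-of-range drives and a response at
  contrast 0 all raise classed errors (`polardrum_error`).
* Renders are deterministic: identical spec, geometry and seed give
  bit-identical frames; reports and manifests contain no timestamps so
  reruns are byte-identical.
* Test and verification problem sizes are chosen to exercise full-scale
  panels where it matters (192×148 px for the renderer round trips) and
  reduced sizes elsewhere (e.g. 96×74 px for stripe-width properties,
  64×64 polarimetric stacks), keeping the full suite in the tens of
  seconds.

## Known limitations

* Loom behavioural categories (0–3) are carried as an opaque data type;
  no automatic classifier is provided because the category semantics are
  observer-defined.
* The screen calibration between its anchored endpoints is a model
  default, not a measurement; supply a measured table for quantitative
  interior-drive work.
* No refraction model for water-filled glass enclosures, no circular
  polarization (Stokes V), no Mueller-matrix instrument calibration, no
  spectral dependence, and no real-time display or projector control.
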