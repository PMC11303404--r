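---
title: "Closed-eye pupillometry and gaze estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-eye pupillometry and gaze estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swirpupil)
```

## The measurement problem

Short-wave infrared (SWIR, ~0.9–1.7 µm) light partially penetrates the
eyelid, so a SWIR camera sees a diffuse dark disc where the pupil sits even
when the eye is shut. `swirpupil` implements an analysis chain that turns
this weak optical signature into quantitative physiology:

* the **fixed-circle darkness** statistic — mean inverted pixel intensity
  inside a static circle covering pupil and iris — which proxies pupil
  *area* without any segmentation and therefore survives the loss of sharp
  pupil borders behind the lid;
* **blink removal and zero-phase filtering** of the darkness traces;
* stimulus-locked **epoching and the robust-PLR criterion** for the
  pupillary light reflex (PLR);
* a **linear darkness-to-diameter calibration** transferring open-eye
  ground truth to closed-eye traces;
* pupil-position **gaze estimation** in degrees of visual angle (DVA) with
  a segment-shuffle surrogate test;
* a small convolutional **encoder-decoder** that reconstructs open-eye
  frames from closed-eye frames, with a forehead-region control model.

Because no recordings of this kind are publicly deposited, the package
ships a first-class **synthetic session generator** that emulates the
optical and statistical structure of such experiments and provides exact
ground truth. Every claim the test suite makes is a claim about this
generator; the section "What the simulator does and does not capture"
delimits what that implies for real data.

## The synthetic session generator

### PLR kinetics

The generator drives the true pupil diameter with a piecewise-exponential
response. While the stimulus light is on (after a latency), the diameter
relaxes toward `baseline − amplitude` with the constriction time constant;
after light offset it re-dilates toward baseline with a slower time
constant:

d(t) = (b − A) + (d₀ − (b − A))·e^(−(t−t₀)/τc)  (light on)
d(t) = b + (d₁ − b)·e^(−(t−t₁)/τr)       (after offset)

with defaults baseline b = 5 mm, amplitude A = 1 mm, latency 0.25 s,
τc = 0.4 s, τr = 4 s. The asymmetry τr ≫ τc reproduces the
characteristic sharp constriction followed by gradual re-dilation; each
excursion starts from the current diameter, so traces are continuous. If a
stimulus arrives before the previous excursion has decayed below 5% of the
amplitude the generator refuses, naming the offending onset pair — at the
default 20 ± 2 s inter-stimulus intervals this never triggers.

The default PLR protocol is ten 2 s uniform-light stimuli at 20 ± 2 s
intervals in a 240 s session sampled at 31 Hz; the gaze protocol is a 15 s
central-fixation baseline, eight crosshair targets (a 3×3 grid minus the
bottom-centre position, which a camera would obscure) shown 5 s each and
repeated twice, plus 10 s of terminal padding, 105 s in total.

### Scene rendering and eyelid optics

Frames are rendered as a dark pupil disc (intensity 0.05) on an iris
annulus (0.55) on bright sclera (0.85), rasterized by
pixel-centre-in-disc membership at 0-based pixel coordinates (x = column
rightward, y = row downward, centres at integers). The closed-eye scene is

closed = clip(blur(open, σ) · transmittance + lid_brightness) + noise,

defaults σ = 3 px, transmittance 0.35, lid brightness 0.45, per-pixel
Gaussian noise 0.01. This is the simplest model that preserves the premise
the fixed-circle statistic relies on: behind the lid, mean darkness within
the circle remains strictly increasing in pupil area (a tested invariant).
Real eyelid transmission spectra and contrast at 1100 nm are not publicly
characterized; these defaults are not claimed to match them. The forehead
control scene is a static smooth texture plus sensor noise, with no pupil
dependence by construction.

The gaze model is a spherical-eye approximation: a rotation of θ displaces
the pupil centre by r_eye·sin θ per axis with r_eye = 12 mm. Target
offsets are specified in image-aligned axes (y increases downward, like
image rows), so displacement carries the same sign as the offset on both
axes and the fitted DVA ratios are positive by construction.

Blinks are injected as brightness transients (+0.3 intensity, saturating
at 1) of 0.2 s, at ~3 per minute with a 2 s minimum separation — enough to
dominate the trace variance the way real blinks do, which the single-pass
detection rule below presumes. Each session takes one integer seed;
independent child streams drive blink placement and pixel noise, so the
ground-truth dynamics are seed-invariant and the rendered stacks are
bit-reproducible.

### Trace-level shortcut

For statistical calibration experiments that need thousands of replicates,
`simulate_darkness_trace()` maps the true diameter through the closed-form
darkness of the rendered geometry (continuous areas instead of pixel
sums) and adds white trace-level noise, default SD 0.002. That value is
deliberately above the shot-noise floor of the rendered ROI mean
(≈2×10⁻⁴) to stand in for residual head-micromovement and illumination
fluctuations; with the default 1 mm amplitude it leaves a per-sample SNR
of ≈6, comfortably detectable after trial averaging, which is what
"default SNR" means throughout the tests.

## The measurement chain

**Darkness.** `mean_circle_darkness()` averages 1 − intensity over pixels
whose centres fall inside the circle; no anti-aliased partial pixels
(values differ from the continuous ideal by O(1/radius), and the choice is
irrelevant to every correlation-based statistic). Darkness is defined as
1 − normalized intensity; any affine definition would give identical
correlations and t statistics.

**Blink removal.** Samples of the ROI mean-intensity trace above
mean + 1 SD are flagged, in a single pass: statistics are not re-estimated
after removal. Contiguous flags merge into one event. The average blink
duration is measured on the average of 1 s windows centred on each event
(window centres at the event midpoint, which keeps identically shaped
blinks aligned under noise) as the width of the profile at 95% of its
peak height above the window baseline — read as "95% of the peak", the
strict reading; the alternative "width containing 95% of the excursion"
reading would give much wider windows for sharp blinks and was rejected.
Flagged events are excised by linear interpolation between the last
sample before and first sample after a window of the estimated duration
(always covering the flagged run), with nearest-value extension and a
warning at trace boundaries. Note a structural property of the mean+1SD
rule: it presumes blinks dominate the trace variance. On a blink-free
trace the PLR constrictions themselves can exceed the threshold; the
pipeline is therefore validated under realistic blink rates.

**Filtering.** A 4th-order Butterworth low-pass (default 1 Hz) applied
forward and backward: zero phase, squared magnitude, DC gain 1. Edges are
handled by odd-reflection padding of 3·fs/cutoff samples and steady-state
initial conditions at the pad edge value; on shared inputs the output
matches the standard forward-backward reference implementation to
numerical precision, including its characteristic edge behaviour on
off-phase pure tones.

**Epoching and statistics.** Epochs run from −2 s to +18 s around each
onset (620 samples at 31 Hz); trials whose window overruns the recording
are dropped with a warning — which is how a 10-stimulus session yields 9
usable events when the last epoch runs off the end. Baseline subtraction
uses the [−2, 0) s mean, excluding the onset sample. The robust-PLR
criterion pairs, per trial, the mean darkness at maximal constriction
(1.5–2.5 s) with the pre-stimulus baseline mean and applies a two-tailed
paired t test across trials; trial-level pairing avoids the autocorrelation
inflation sample-level pairing would suffer. Open/closed concordance is the
Pearson correlation of the average event time courses, taken to group
level by the variance-stabilizing Fisher transform and a one-sample t test
against zero.

**Calibration.** Ordinary least squares of diameter on darkness, fitted on
baseline-relative averaged PLR events (concatenated-trial fitting is
available by flag). Diameter from area (equivalent circle), not horizontal
extent, which is robust to non-circular pupils. The relation is affine in
*area*, so over a 1 mm excursion around a 5 mm baseline the linear
diameter fit retains R² ≈ 0.99; its residual curvature is part of the
tested error budget.

**Gaze.** Pupil centres come from percentile-threshold segmentation:
largest connected dark component, centroid, equivalent-area diameter. Two
thresholds serve two purposes: sizing uses the 10th-percentile intensity
(robust to global brightness), while *centre* estimation uses the darkest
2% core — near the iris boundary, eyelid blur tilts brightness across the
pupil and biases centroids taken over looser thresholds by ~2 px, whereas
the compact core stays symmetric. The (0,0) origin is the median centre
over central-fixation frames; positions are origin-subtracted, scaled to
mm, and mapped to DVA by per-axis least-squares slopes through the origin
("calibration ratio" — proportional, not affine, because a zero offset at
the origin is part of its definition). Reference angles are
atan(offset/distance). Error statistics use target-display frames with the
first 0.5 s of each dwell trimmed (gaze transitions); whether to include
transition frames is a genuinely open choice and the trim is configurable.
The surrogate test permutes non-overlapping one-dwell-length segments of
the closed-eye trace and uses the add-one-corrected p-value, which is
super-uniform under the null by construction.

**Reconstruction network.** A 3-level fully convolutional encoder-decoder
(3×3 convolutions, ReLU, 2×2 average pooling, nearest-neighbour
upsampling, skip concatenations at both levels) with the raw input frame
concatenated into the final 1×1 convolution — a global residual path that
makes identity mappings exactly representable. Default widths 16/32/64
(8/16/32 at cohort scale), MAE loss, Adam at learning rate 10⁻³ (an
unreported free choice), batch 8, early stopping on two held-out
validation events with the canonical nine-event split: test {5, 7},
validation {4, 6}, remainder train; other event counts map the positions
proportionally. Frames are z-normalized per frame before entering the
network; predictions are de-normalized with the mean statistics of the
training targets — an affine choice that downstream quantile/midpoint
segmentation is invariant to. Training is bit-deterministic given the
seed (own Mersenne Twister stream for init and shuffling). Pupil diameter
is extracted from predicted frames with the *midpoint* threshold (halfway
between the 2nd-percentile core and 25th-percentile iris level): on
smooth reconstructions a fixed-fraction quantile threshold would count a
constant 10% of pixels as pupil, an artifact, while the half-maximum
contour remains meaningful; prediction traces are 1 Hz low-passed before
scoring, and a model whose segmentation fails on more than half its
frames is marked failed. Scoring follows the baseline-relative
convention used everywhere else: both the predicted and the true
diameter of each test event are expressed as mm changes from that
event's 2 s pre-stimulus baseline before the MAE, which also removes the
shared absolute offset that segmenting smooth reconstructions imposes on
both models alike.

## Problem sizes

The validation suite runs everything at desk scale, chosen once as
realistic miniatures of the full protocols: trace-level statistical
calibration at the full 31 Hz (1,000 null and 200 signal replicates of
nine-trial sessions); rendered PLR sessions of five stimuli at 8 Hz and
96×96 px; the full 105 s gaze protocol at 8 Hz; and an
eight-session reconstruction cohort at 64×64 px and 8 Hz with nine
20 s-spaced stimuli per session, ~100 training frames per model and 16
epochs (identity checks at 32×32, 40 epochs). Rendering at the full
240 s × 31 Hz is supported and tested for bookkeeping (7,440 frames) but
not needed by any statistical claim.

## What the simulator does and does not capture

It captures: the darkness–area link behind a scattering lid, asymmetric
PLR kinetics with trial jitter, blink-like brightness transients, grid
fixations with a geometric eye-rotation model, a pupil-independent control
region, and seeded sensor noise. It does not capture: photorealistic SWIR
speckle, eyelash/skin texture, head motion, pupil-size-dependent gaze
artifacts (the pupil is rendered circular), radiometric units, spectral
eyelid transmission, or inter-subject variability in any of these. Tests
passing on this generator therefore demonstrate the *correctness and
calibration of the algorithms* under the stated model, not their field
performance on human recordings; headline numbers from such recordings
(robust-PLR prevalence, concordance levels, millimetre gaze errors) are
not reproducible from synthetic data and are not asserted anywhere in the
suite.

## Numerical and design choices, in brief

* Rasterization by pixel-centre membership everywhere; noiseless plateaus
  that coincide exactly with a threshold quantile fall back from strict to
  closed comparison in segmentation.
* The exclusion statistic (horizontal position SD over time) uses the
  sample standard deviation (n−1); the threshold is mean + 1 SD across
  sessions with strict exceedance, so identical sessions are all kept.
  Sessions are treated independently (not pooled within participant).
* `epoch_events` drops overrunning trials rather than shortening them, so
  all rows share one time axis.
* Degenerate inputs error loudly: constant traces in correlation or
  calibration, |r| = 1 in the Fisher test, fewer than 2 sessions in the
  exclusion rule, fewer than 3 trials in the robust-PLR test, constant
  frames in normalization.
* The surrogate p uses the (1 + #{≤})/(1 + n) correction; with k segments
  only k! distinct alignments exist, so very short sessions floor the
  attainable p.
* Deviating from a fixed-fraction threshold for reconstructed frames (the
  midpoint rule above) was a correctness decision, not a tuning one: the
  quantile rule is ill-posed on unimodal smooth images.

## Known limitations

The package analyses one eye per scene and assumes the pupil stays within
the iris disc under the largest rendered gaze deflection. The blink rule
is the single-pass mean + 1 SD criterion by design and will misfire on
traces whose variance is not blink-dominated. The encoder-decoder is a
per-session model; no attempt is made to generalize across sessions or to
real SWIR imagery. Segmenting smooth
predictions biases the absolute diameter upward; the baseline-relative
scoring cancels it within the paired comparison, but absolute predicted
diameters should not be read off the reconstruction without an
open-eye calibration.
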