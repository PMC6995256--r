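---
title: "Localizing the dynamic body-selective network: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing the dynamic body-selective network: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynbodyloc)
```

## The problem

Static body localizers (bodies versus objects in still images) find the
extrastriate and fusiform body areas (EBA, FBA) but miss the regions
driven by bodies *in motion* — the posterior superior temporal sulcus
(pSTS), precentral gyrus (PCG) and inferior frontal gyrus (IFG) — which
have traditionally required a separate point-light-display run.
A single block-design run contrasting *dynamic* bodies against *dynamic*
objects can localize the whole network at once, provided low-level
visual motion is controlled: if the body clips simply move more than the
object clips, "body-selective" voxels may just be motion-selective.
This package implements that localizer as a tested pipeline: a pixelwise
clip-motion measure entered into the GLM as a covariate, an m-sequence
block schedule, voxelwise OLS with contrast t-maps, and threshold-based
ROI extraction — together with a synthetic-data module that makes every
stage testable against planted ground truth.

## The clip-motion measure

For each clip, the frame-to-frame change in luminance within the green
background (RGB 159, 202, 145; pixels never occupied by the figure) is
used as a surrogate for the clip's noise level. Then, for every pair of
consecutive frames, the measure counts the pixels of the *whole* frame
whose absolute luminance change exceeds that noise level, and averages
the counts into one value per clip. Cumulative motion for a 10-s block
is the sum over its five clips.

Choices the measure's verbal description leaves open, and what this
package does:

* **Luminance.** Rec.601 weighting, `0.299 R + 0.587 G + 0.114 B`.
  Weights sum to one, so grayscale sources pass through unchanged.
* **Noise statistic.** The default is the mean over frame pairs of the
  95th percentile of background `|Δ luminance|`. For i.i.d. Gaussian
  pixel noise of sd σ the differences are half-normal with scale σ√2,
  so the statistic estimates `1.96·σ√2` — a stable high quantile that
  sits well below genuine object motion. `mean` and `mean + 2·sd`
  variants are available (`estimate_noise(stat = )`), since a scalar
  noise summary admits several defensible definitions.
* **Signed vs absolute change.** Absolute change is used; a count of
  signed changes would depend on the direction of figure/ground
  contrast.
* **Counting region.** The whole frame is counted (the border region is
  static anyway up to noise); restricting to a mask is possible by
  thresholding manually against `clip_motion(clip, noise_level)`.

The degrees of freedom of the body-versus-object block comparison are
reported from the data, never fixed, because with 18 blocks per
condition a pooled two-sample test has 34 degrees of freedom; the
package makes no attempt to reproduce any particular historical value.

## Synthetic clips: what the generator emulates

`make_clip()` renders a dark rigid object translating one pixel per
frame across a uniform green background (default geometry 960 × 540 px,
50 frames at 25 fps — a two-second clip), then adds zero-mean Gaussian
noise. Two design decisions make the ground truth analytic:

* A rigid object of edge length *s* translating one pixel changes
  exactly *2s* pixels per frame pair on a clean background, so
  `moving_pixels_per_frame = 2s` is exact by construction.
* Noise is a single Gaussian deviate added identically to all three
  channels of a pixel, so the luminance noise sd equals `noise_sd`
  exactly (the Rec.601 weights sum to one). The clip records its
  *realized noise level* — the maximum `|Δ luminance|` over all pixels
  not moved by the object — so the supra-noise count at that threshold
  equals the planted count exactly, with no statistical slack.

What the generator does **not** emulate: articulated human figures,
emotional movement kinematics, compression artifacts, camera shake, or
spatially correlated sensor noise. Passing the oracle tests therefore
shows that the *counting machinery* is exact, not that the measure
captures perceived human motion; on real clips the noise statistic and
the correlation with ratings carry that burden.

`make_ratings()` constructs rating vectors with an exactly prescribed
sample correlation (standardized motion vector plus an orthogonalized
noise component in closed form), used to exercise the validation
statistics at, e.g., `target_r = 0.571` with `n = 61` pairs.

## The block schedule

One run is 48 ten-second blocks: 18 body (balanced across angry, happy,
neutral), 18 object, 12 blank baseline, pseudo-randomized from an
m-sequence over GF(3). The package generates true maximal-length LFSR
sequences (shipped taps verified primitive for orders 2–4; a
non-primitive tap set is rejected with its realized period). Because the
full period of an order-3 sequence is 26 and the composition 18/18/12 is
not the m-sequence's symbol balance, the cyclic sequence is tiled to 48
and the counts are repaired by single-block edits chosen to minimize
lag-1 condition agreement, under a hard cap of three consecutive
same-condition blocks. This preserves the decorrelation intent while
matching the printed composition exactly; the realized body–object
regressor correlation of the shipped schedule is about −0.39 and the
design is full rank. An 18-body run cannot hold three blocks of each of
three emotions, so the balanced 6/6/6 rotation is used, exposed via the
`emotions` argument. Blocks abut at exactly 10-s spacing (no gap is
modeled), giving a 480-s schedule inside the 639.6-s acquisition
(246 volumes × 2.6 s); the remaining time is baseline.

## The GLM

The design matrix contains, in order: HRF-convolved 10-s boxcars for
body and object ("non-body"), the motion covariate, six mean-centered
head-motion regressors, a discrete-cosine drift basis, and an intercept.

* **HRF.** The canonical double-gamma,
  `h(t) = g(t; 6, 1) − g(t; 16, 1)/6`, peak normalized to one, peaking
  near 5 s. No derivative terms are included: the localizer contrast is
  a block-level amplitude question.
* **Motion covariate.** A boxcar whose height during each stimulus
  block is that block's mean-centered cumulative motion, convolved with
  the HRF (`covariate_mode = "raw"` enters the unconvolved per-scan
  boxcar instead, for users who prefer scan-level covariates). Centering
  means that when all blocks carry identical motion the column is
  exactly zero and is absorbed harmlessly — the fit then uses a
  pseudoinverse and the body-minus-object t is unchanged.
* **Drift.** `K = floor(2·T/cutoff)` orthonormal DCT columns for a run
  of length `T` seconds; at 246 × 2.6 s and the 128-s default cutoff,
  `K = 9`. `highpass_filter()` applies the same projection directly to
  a series, so the two routes are consistent by construction.
* **Smoothing.** Separable Gaussian, FWHM 8 mm by default
  (σ = 8/(2√(2 ln 2)) ≈ 3.40 mm per axis), unit-mass kernel with zero
  padding: total intensity away from the volume edge is conserved.
* **Estimation.** Per-voxel OLS via QR, `df = n − rank(X)`;
  `t = c′β̂ / √(σ̂² c′(X′X)⁻¹c)`. Voxels with numerically constant data
  are flagged and given t = 0; perfect fits (noise-free synthetic data)
  are capped at |t| = 10⁸ rather than returning infinities. No AR(1)
  prewhitening is applied — for a 10-s block design the contrast
  estimate is dominated by low-frequency structure the DCT basis
  handles, and the calibration simulations below confirm nominal false
  positive rates under white noise (under strongly autocorrelated noise
  the uncorrected rates would be optimistic; that is a known limitation).
* **Group level.** Per-subject contrast images enter a one-sample t
  (df = subjects − 1), the degenerate form of a second-level ANOVA with
  a single contrast.

## Thresholding and ROI extraction

Maps are thresholded one-sided at three nested levels — p < .05
voxel-level FWE, p < .001 uncorrected, p < .05 uncorrected — each with a
10-voxel cluster-extent minimum (6-connectivity by default; 18 and 26
available). FWE is controlled by Bonferroni over the search mask, with a
sign-flip max-T permutation alternative (`maxt_threshold()`) that is
exact under symmetric exchangeability at the group level. Random-field
theory, which SPM uses for the same purpose, is deliberately out of
scope: its smoothness estimation machinery is disproportionate here, and
Bonferroni's conservativeness is verified by simulation rather than
assumed. Absolute thresholds therefore differ somewhat from an SPM
analysis of the same data.

ROIs are extracted within 10-mm spheres around the seven canonical
network coordinates (`default_roi_seeds()`: rFBA, rEBA, rpSTS, rPCG,
lEBA, lpSTS, rIFG); the peak is the maximum-t surviving voxel, ties
broken by first voxel in lexicographic index order, and a region with no
surviving voxel is reported absent, not an error. Per-subject presence
requires surviving *both* height and extent thresholds. Group summaries
tally subjects showing activation per ROI and threshold, and
`compare_to_reference()` reports millimetre distances to
literature-average coordinates (`literature_roi_coords()`).

## Synthetic BOLD and problem sizes

`make_bold()` plants HRF-convolved condition responses in 6-mm spherical
neighbourhoods (≈ 33 voxels at 3 mm — comfortably above the 10-voxel
extent), over a constant baseline of 100, with optional linear +
low-frequency cosine drift, six smooth random-walk head-motion traces
coupled to voxels with standard-normal weights, and i.i.d. Gaussian
noise. The recorded traces can be fed back as confound regressors,
exercising nuisance regression with a known answer. With zero noise the
planted time course and GLM recovery are exact to numerical precision.

The spec'd default grid is 20 × 24 × 20 voxels at 3 mm with the grid
centre at the MNI origin — adequate for unit-scale work, but the seven
canonical seeds span x ∈ [−63, 54], y ∈ [−79, 20], z ∈ [−17, 46] and lie
outside it. The grid centre is therefore configurable, and
`demo_synthetic()` uses 50 × 44 × 32 voxels centred at (0, −25, 10) mm,
the smallest round grid containing every seed's 10-mm search sphere.

Problem sizes used by the shipped checks, chosen to keep a full run in
the low tens of seconds on one core while leaving Monte-Carlo error well
inside the tolerances tested: 50 oracle clips at 130 × 90 px; GLM oracle
on 10³ voxels; null calibration on 200 runs of a 12³ grid (the mean
supra-threshold fraction at p < .05 then has standard error ≈ 0.0004)
and Bonferroni familywise control on 500 runs of a 10³ grid; end-to-end
recovery with 3 subjects at amplitude 5 × noise sd. The familywise check
is a one-sided binomial bound (count ≤ the 99.9% binomial quantile at
rate .05 over 500 runs) because the sample rate of an exactly calibrated
procedure exceeds its own nominal level in roughly half of finite
experiments; the bound tests conservativeness without being vacuous.

## Known limitations

* White-noise error model (no AR(1)); uncorrected thresholds are
  optimistic under strong temporal autocorrelation.
* Bonferroni FWE is conservative relative to random-field theory on
  smooth maps; reported FWE voxel counts will be smaller than an SPM
  analysis at the same nominal level.
* The pipeline consumes already-registered volumes: realignment,
  coregistration, segmentation and MNI normalization are upstream and
  out of scope, as is stimulus presentation.
* Synthetic clips are rigid-translation stimuli; they validate the
  counting machinery, not the perceptual validity of the motion measure.
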