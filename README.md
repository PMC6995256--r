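# dynbodyloc

An R implementation of a **dynamic body-selective area fMRI localizer**:
a single block-design run contrasting dynamic body clips against dynamic
object clips that localizes the *entire* body-processing network — the
extrastriate and fusiform body areas (rEBA, lEBA, rFBA) that static
localizers find, **and** the body-motion regions (rpSTS, lpSTS, rPCG,
rIFG) that normally require a separate point-light-display run.

The key methodological ingredient is control of low-level visual motion:
each clip's motion is quantified by counting, for every pair of
consecutive frames, the pixels whose absolute luminance change exceeds
the clip's background-noise level, averaged to one value per clip and
summed over the five clips of each 10-s block; the per-block cumulative
motion enters the voxelwise GLM as a covariate so that "body > object"
activation cannot be driven by the stimuli simply moving differently.

The package is aimed at researchers building or validating block-design
localizers: it covers stimulus motion quantification, m-sequence
schedule generation, GLM fitting with nuisance regressors, thresholded
ROI extraction — and a synthetic-data module that generates
motion-controlled video clips and 4D BOLD volumes with planted ground
truth, so the full pipeline is testable end to end without scanner data.

## The model

Per voxel, the BOLD time series `y` (246 volumes, TR 2.6 s) is modeled
by OLS as

```
y = β_body (body ⊛ h) + β_obj (object ⊛ h) + β_m (motion ⊛ h)
    + Σ_j γ_j m_j + DCT drift (cutoff 128 s) + intercept + ε
```

where `h` is the canonical double-gamma HRF
(`g(t;6,1) − g(t;16,1)/6`, peak ≈ 5 s), `body`/`object` are 10-s block
boxcars, `motion` is a boxcar carrying each block's mean-centered
cumulative clip motion, and `m_1..m_6` are head-motion parameters. The
localizer contrast is `t = c′β̂ / √(σ̂² c′(X′X)⁻¹c)` with
`c = body − object`, thresholded one-sided at p < .05 voxel-level FWE
(Bonferroni; sign-flip max-T available), p < .001 and p < .05
uncorrected, each with a 10-voxel cluster-extent minimum; ROI peaks are
extracted within 10-mm spheres of seven canonical MNI coordinates.

The experimental run is 48 ten-second blocks — 18 body (6 angry, 6
happy, 6 neutral), 18 object, 12 baseline — ordered by a maximal-length
shift-register sequence over GF(3), count-repaired with minimal edits
under a cap of three consecutive same-condition blocks.

## Worked example

```r
library(dynbodyloc)

# 1. quantify motion in a synthetic clip with 120 truly moving pixels/frame
clip <- make_clip(clip_spec(width = 200, height = 100, n_frames = 20,
                            noise_sd = 2, moving_pixels_per_frame = 120,
                            seed = 1))
clip_motion(clip)
#> motion_result: clip_motion = 120.00 (noise level 13.92, 19 frame pairs)
```

The clip's ground truth is 120 supra-noise pixels per frame pair (a
60-px rigid object translating 1 px/frame changes exactly 2 × 60
pixels); the measure recovers it exactly at the clip's realized noise
level (13.92 luminance units — the largest frame-to-frame change among
pixels the object did not touch).

```r
# 2. the 48-block m-sequence schedule
schedule <- build_schedule(seed = 1)
table(schedule$blocks$condition)
#>     baseline   body_angry   body_happy body_neutral       object
#>           12            6            6            6           18

# 3. fully synthetic end-to-end run: 3 subjects, activations planted at
#    the seven canonical coordinates at 5x the noise sd (~40 s)
res <- demo_synthetic(seed = 42, n_subjects = 3)
subset(res$group_tally, threshold == "unc_001")
#>      roi threshold n_present n_subjects frac_present mean_n_voxels mean_x mean_y mean_z ...
#> 8   rFBA   unc_001         3          3            1           160   45.5  -45.5  -16.5
#> 9   rEBA   unc_001         3          3            1           160   46.5  -78.5  -10.5
#> 10 rpSTS   unc_001         3          3            1           160   53.5  -46.5    7.5
#> 11  rPCG   unc_001         3          3            1           160   48.5    3.5   44.5
#> 12  lEBA   unc_001         3          3            1           160  -49.5  -72.5    6.5
#> 13 lpSTS   unc_001         3          3            1           160  -63.5  -48.5   19.5
#> 14  rIFG   unc_001         3          3            1           160   41.5   20.5   23.5
```

All seven regions are detected in every synthetic subject at
p < .001 uncorrected, with group-mean peaks within one voxel of the
planted coordinates (e.g. rFBA planted at (45, −46, −17), recovered at
(45.5, −45.5, −16.5)); `res$motion_stats$rating_correlation$r` is
`0.571`, the correlation at which the synthetic perceived-motion
ratings were generated.

Real data enter through the same functions: `run_localizer()` takes
NIfTI 4D volumes, a BIDS-style events TSV, a block-motion TSV and
6-column head-motion files, and writes t-maps, ROI reports and a
provenance JSON. A thin CLI wraps the same calls:

```sh
Rscript inst/cli/dynbodyloc.R design --seed 1 --out events.tsv
Rscript inst/cli/dynbodyloc.R simulate --seed 42 --subjects 3 --out-dir demo/
Rscript inst/cli/dynbodyloc.R run --bold sub01.nii.gz --events events.tsv \
    --motions blocks.tsv --confounds mp01.txt --out-dir out/
```

See `vignettes/dynamic-body-localizer.Rmd` for the full account of the
model, the tunable parameters and the numerical design choices.

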