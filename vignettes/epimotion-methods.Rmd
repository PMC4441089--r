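---
title: "Quantifying motion relative to k-space encoding in 3D EPI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motion relative to k-space encoding in 3D EPI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(epimotion)
```

## The problem

Multi-shot 3D EPI acquires one k_x-k_y plane ("partition") of 3D k-space
per RF excitation, so a whole image volume takes seconds to assemble
(44 partitions x 78 ms TR = 3.4 s in the protocol modelled here). Head
motion during that window corrupts the shared 3D Fourier encoding, and
the damage depends not just on how much the head moved but on *when* it
moved relative to the partition ordering: motion coincident with the
energetic centre of k-space is far more destructive than the same motion
during the periphery. Prospective motion correction (PMC) with an
in-bore optical camera counteracts this by realigning the imaging
field of view to the tracked head pose immediately before every
excitation.

epimotion implements the analysis side of such an experiment — motion
metrics computed from tracker logs, tSNR/RMSE image-quality pipelines,
and a saturating-exponential artifact model — together with a digital
acquisition simulator so the whole chain can be exercised and tested at
desk scale with known ground truth.

## Motion metrics

The camera logs six pose channels at 80 Hz: translations x, y, z in mm
and rotations pitch, roll, yaw in degrees. The pipeline is:

1. **Low-pass filter** (`lowpass()`): a zero-phase (forward-backward)
   Butterworth filter with a 10 Hz cutoff removes mechanical scanner
   vibration, which in 3D EPI sits at the partition repetition frequency
   1/TR = 12.8 Hz. We use order 5 per pass: at 80 Hz sampling a 4th-order
   zero-phase design attenuates 12.8 Hz by only ~20 dB in amplitude,
   leaving no margin against spectral leakage in finite traces, while
   order 5 gives ~25 dB and still passes 1 Hz head motion unchanged.
   Channels are mean-centred and reflection-padded before filtering so a
   constant pose passes through exactly (DC gain 1) and start-up
   transients do not leak into the metric.
2. **Total speed** (`total_speed()`): the root-sum-square of the six
   channel derivatives, S = sqrt(dx² + dy² + dz² + dP² + dR² + dY²)
   (dots denote time derivatives). Degrees are weighted equally with
   millimetres, which equals assuming a 180/pi mm ≈ 5.7 cm rotation
   radius — a reasonable head radius. Central differences (one-sided at
   the ends) keep the series at camera resolution.
3. **Integrated motion** M (`integrated_motion()`): the rectangle-rule
   integral of S over each volume's acquisition window, one
   mm-equivalent scalar per volume.
4. **Partition weights** k_j (`partition_weights()`): the reference
   magnitude image is Fourier transformed and |c|² summed over each
   k_x-k_y plane. Taking the magnitude image imposes an artificial
   conjugate symmetry on k-space (a few percent effect on the weights),
   accepted in exchange for not having to store raw multi-channel
   k-space.
5. **Partition-weighted integrated motion** M_PW
   (`partition_weighted_motion()`): the same integral with every speed
   sample weighted by the k_j of the partition being acquired at that
   instant. A camera sample belongs to the partition whose half-open
   [start, start + TR) interval contains its timestamp, so the intervals
   tile each volume window exactly and M_PW reduces to M identically
   under uniform weights.

**Weight normalization.** As printed, k_j carries units of summed
squared image intensity, yet M_PW is reported in mm. We normalise the
weights to mean one by default (`mean_one`), which keeps M_PW on the
same mm-equivalent scale as M, makes the two directly comparable, and
is consistent with reported motion levels (no-motion ≈ 2 mm, slow ≈ 8,
fast ≈ 14-16 per volume) and with 2.5 mm binning of M_PW. `sum_one` and
`raw` are retained as options.

## The synthetic trace generator

`generate_trace()` emulates the coached-volunteer conditions of a PMC
validation run; its defaults *are* those study conditions, not free
dials:

* **Regimes**: `none`, `slow` (peak combined speed drawn from
  10-15 mm-equiv/s) and `fast` (40-50 mm-equiv/s).
* **Bursts**: raised-cosine (Hann) out-and-back excursions on the three
  translations plus usually one rotation channel. The shape is C¹, so
  burst onsets do not inject spurious high-frequency speed, and the peak
  combined speed of a burst with duration T and amplitude vector A is
  analytically pi·||A||/T, which lets us calibrate the drawn peak speed
  exactly. Burst durations are ~1.8 s (slow) and ~0.75 s (fast), onsets
  follow a Poisson process (10 and 12 bursts/min) thinned to keep at
  least the configured still fraction (60%), and the first 12 volumes
  stay still so an artifact-free reference can be built. These rates
  integrate to mean per-volume M_PW of ≈ 2 (none, from the noise floor),
  ≈ 8 (slow) and ≈ 14-16 (fast), the levels the coached experiments
  produce.
* **Bounds**: the coached ±10 mm / ±5° range is treated as a hard
  constraint (volunteers watched their own traces in real time), so
  burst amplitudes reserve headroom for vibration and noise, amplitudes
  exceeding a channel bound are clipped with their energy redistributed
  over the remaining channels (preserving the drawn peak speed), and the
  final trace is clipped to the bounds.
* **Vibration and noise**: a 12.8 Hz sinusoid (0.05 mm) on the
  translations models mechanical scanner vibration; white Gaussian noise
  (SD 0.015 mm/deg on all channels) models tracker precision. After the
  10 Hz low-pass this floor integrates to ≈ 2 mm-equivalent of M_PW per
  3.4 s volume — the level still subjects show.

What the generator does **not** emulate: the spectral shape and axis
coupling of real volunteer motion (unreported), marker-skin decoupling,
camera dropouts, or slow physiological drift. Tests passing on these
traces show the *pipeline* behaves correctly, not that real heads move
like raised cosines.

## The acquisition simulator

`simulate_series()` acquires one k_z plane per TR from a digital phantom
(Gaussian blob, 3D Shepp-Logan, or a multi-ellipsoid phantom with
internal contrast), posed per the trace at each excitation's start time
(nearest camera sample at or before it, mirroring update-before-
excitation semantics):

* **Hybrid transform handling**: rotations are applied by trilinear
  resampling in image space before the FFT; the residual translation is
  applied as an exact phase ramp on the extracted k-plane. This makes
  pure-translation simulations agree with the Fourier-shift theorem to
  machine precision and confines interpolation error to rotations.
* **Small-rotation path**: poses whose rotation angles are all below
  `min_rotation` (default 0.02°) are applied as their equivalent
  translation about the rotation centre. At tracker-noise angles the
  trilinear interpolation error would exceed the true rotation effect —
  a real scanner rotates its gradients exactly — so this is both faster
  and more faithful.
* **PMC**: with correction on, the pose is composed with the inverse of
  the camera-reported pose at `t - pmc_latency`. The camera is perfect
  by assumption; latency is the knob that degrades it. Zero latency
  cancels motion exactly (a useful oracle); the factorial runner
  defaults to one camera frame (12.5 ms), the staleness of the newest
  pose available when the FOV is updated immediately before an
  excitation. We do not use a full-TR lag: sign-erratic partition-to-
  partition residuals of a 78 ms lag under fast motion ghost *worse*
  than smooth uncorrected excursions, which contradicts the behaviour
  of the real update scheme.
* **Not modelled** (by design): GRAPPA undersampling (k-space is fully
  sampled; the high-resolution protocol is represented by matrix size
  only), partition oversampling, slab excitation profiles, T2* decay
  within the echo train, B0 distortion, coil sensitivities, spin
  history, physiological noise. Image noise is white Gaussian in image
  space, with SD expressed as a fraction of the mean intensity over the
  phantom support (default 2%, which yields no-motion tSNR ≈ 50-65,
  the plausible thermal-noise regime of a 3 mm protocol).

## Image-quality pipeline

`quality_pipeline()` mirrors the standard per-run analysis: realign all
volumes rigidly to the first, discard the first 5 volumes, derive
partition weights from the mean of the remaining baseline volumes
(volumes 6-12 in the original numbering — the instructed-still period
minus the discard), compute M/M_PW from the 10 Hz-filtered trace,
build the reference image as the voxelwise mean of all volumes whose
M_PW is at or below the baseline maximum, mask the brain (intensity
threshold at 20% of the robust maximum, 6-neighbourhood closing,
largest connected component — or the known phantom support for
simulations), scale the whole 4D set by the global in-mask mean, and
report per-volume RMSE against the reference plus voxelwise tSNR
(temporal mean over the SD of linearly detrended residuals; zero-
variance voxels get an Inf sentinel and are excluded from summaries).

**Registration.** The 6-DOF estimate minimises the masked mean squared
difference, evaluated *symmetrically*: both images are resampled by half
the candidate pose (the reference by the inverse half). A one-sided
cost is biased toward the identity — resampling at the identity is
interpolation-error-free — which at 32³ desk scale made ~2° rotations
unrecoverable; the symmetric cost recovers them to ~0.1°. Both images
are lightly smoothed ([1 2 1]/4 per axis) for the cost only, a
Nelder-Mead translation stage precedes full 6-parameter refinement
warm-started from the previous volume, and the simplex is restarted up
to three times when the iteration cap is hit near an optimum. Volumes
that still fail to converge are flagged and passed through
unregistered.

## Artifact model

`fit_saturating()` fits RMSE = A·(1 − exp(−R·M_PW)) by
Levenberg-Marquardt nonlinear least squares (A₀ = max RMSE,
R₀ = 1/median M_PW, both parameters bounded positive). The model is
heuristic — not derived from acquisition physics — chosen because
artifact level must saturate as motion grows. r² = 1 − SS_res/SS_tot is
reported unadjusted: both candidate predictors (M, M_PW) carry two
parameters, so adjustment would cancel in the comparison
(`compare_predictors()`). Ordinary least squares is used; the fits pool
volumes without robustness weighting. `binned_percent_reduction()`
averages RMSE in 2.5 mm-wide M_PW bins (only bins with ≥ 5 volumes in
both conditions), reports (off − on)/off × 100 per bin, and propagates
the per-bin standard errors of the means through the ratio to first
order.

## The factorial runner and problem sizes

`run_factorial()` executes the 2 (PMC) × 3 (regime) design with the
trace *shared* between the PMC-on and PMC-off members of each pair —
something no volunteer can do — so motion levels match exactly; the
pair also shares the partition weights (derived from the first member's
baseline), making the paired M_PW distributions identical by
construction. Each cell runs the full quality pipeline and the runner
returns a Table-style summary (mean in-mask tSNR, mean M_PW per cell),
per-regime predictor comparisons and the binned reduction curve.

The package's own experiments run at 32³ voxels (32 partitions, 3 mm),
40 volumes per cell, with a 100-volume ensemble for the predictor
comparison — sizes chosen so the full factorial completes in minutes on
one CPU while leaving every qualitative contrast (tSNR ordering,
predictor ranking, rising reduction curve) comfortably resolved.
Expected behaviours at this scale, all computed by the test suite and
`scripts/acceptance.R` rather than asserted here: no-motion tSNR agrees
between PMC on and off to a few percent; correction raises tSNR
substantially under slow and fast motion; r²(M_PW) exceeds r²(M) on
uncorrected ensembles; and the percent-RMSE-reduction curve rises from
the lowest to the highest retained M_PW bin.

## Numerical choices and degenerate inputs

* k-space planes are indexed in fftshifted (DC-centred) order so plane
  j maps to the linearly ascending partition-encoding step j; the
  k_z = 0 plane sits at floor(P/2) + 1.
* Trilinear sampling snaps coordinates within 1e-9 of a grid plane so
  integer-voxel translations are exact; points outside the FOV sample
  zero, and transforms that push the support against the FOV edge flag
  the result as clipped.
* Sample-to-partition assignment uses half-open intervals, so no camera
  sample is counted twice and M_PW ≡ M under uniform weights to 1e-9.
* All-zero reference images (undefined weights), zero-variance voxels
  (infinite tSNR), single-sample traces, cutoffs at/above Nyquist,
  non-monotone tracker logs and predictor vectors without spread are
  rejected with explicit errors rather than propagated as NaN.
* Every stochastic component (trace generation, phantom layout, image
  noise) is seeded; identical seeds reproduce traces, series and whole
  factorial summaries bitwise.

## Known limitations

* The artifact simulator omits the physics listed above; absolute tSNR
  and RMSE values are therefore analogues, not predictions, and
  real-data effect sizes (e.g. percent tSNR gains) are reproduced
  directionally, not numerically.
* Rigid-body motion is assumed throughout, as in the modelled system.
* The registration module targets the desk-scale simulated regime; it
  is serviceable, not a drop-in replacement for a production
  neuroimaging realignment tool.
* With near-perfect correction (one-frame latency) and no physiological
  noise, corrected slow-motion series can be almost indistinguishable
  from still ones at small matrix sizes — a deliberately conservative
  regime in which ordering contrasts are weaker than in real data.
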