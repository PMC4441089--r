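# epimotion

Motion metrics and artifact simulation for prospectively corrected
multi-shot 3D EPI fMRI.

## The problem

Multi-shot 3D EPI assembles each image volume one k-space partition
(k_x–k_y plane) per RF excitation — 44 excitations at TR = 78 ms, about
3.4 s per volume in the protocol modelled here. Head motion during that
window corrupts the shared 3D Fourier encoding, and how badly depends on
*when* the motion occurs relative to the partition ordering: movement
during the energetic central partitions destroys far more image quality
than the same movement during the k-space periphery. Prospective motion
correction (PMC) counters this by realigning the imaging field of view
to the optically tracked head pose immediately before every excitation.

epimotion is for researchers evaluating such systems. It implements:

* **Motion metrics** from 80 Hz 6-DOF tracker logs: total speed
  `S = sqrt(ẋ² + ẏ² + ż² + Ṗ² + Ṙ² + Ẏ²)` (mm and degrees weighted
  equally, i.e. a 5.7 cm rotation radius), per-volume integrated motion
  `M = Σᵢ Sᵢ·Δt`, k-space partition energy weights
  `kⱼ = Σ_{kx,ky} |c|²` from a reference image, and partition-weighted
  integrated motion `M_PW = Σⱼ Σᵢ S_{i,j}·kⱼ·Δt`, after zero-phase 10 Hz
  low-pass filtering (scanner vibration sits at 1/TR = 12.8 Hz).
* **A 3D EPI acquisition simulator**: one k_z plane per TR from a
  digital phantom under rigid-body motion, translations as exact k-space
  phase ramps, rotations by image-space resampling, PMC on/off with
  configurable latency, seeded noise.
* **The image-quality pipeline**: rigid realignment to the first
  volume, initial-volume discard, voxelwise tSNR with first-order
  detrending, an M_PW-gated motion-free reference image, brain masking,
  global mean-signal scaling, per-volume RMSE.
* **The artifact model**: `RMSE = A·(1 − exp(−R·M_PW))` fitted by
  nonlinear least squares, r² comparison of M vs M_PW as predictors,
  and percent-RMSE-reduction curves over 2.5 mm M_PW bins.
* **A factorial runner** reproducing the 2 (PMC) × 3 (no/slow/fast
  motion) validation design at desk scale, with the motion trace
  replayed identically for the corrected and uncorrected runs.

## Worked example: motion timing vs k-space encoding

An identical 5 mm, 0.4 s head movement is placed either while the
central partition of a volume is acquired or during the k-space
periphery:

```r
library(epimotion)

ph <- make_phantom(c(32, 32, 32), "gaussian_blob", voxel_size = 3)
tm <- acq_timing(1, partitions_per_volume = 32)
w  <- partition_weights(ph)

mkb <- function(t_on) {           # one raised-cosine x-excursion
  n <- round((tm$volume_duration + 0.3) * 80)
  tt <- (seq_len(n) - 1) / 80
  prof <- ifelse(tt >= t_on & tt < t_on + 0.4,
                 5 * (1 - cos(2 * pi * (tt - t_on) / 0.4)) / 2, 0)
  z <- rep(0, n)
  motion_trace(tt, prof, z, z, z, z, z, 80)
}
central <- mkb((tm$center_partition_index - 1) * tm$tr)
periph  <- mkb(0.05)

mask <- make_mask(ph, provenance = "phantom_support")
for (trc in list(periph = periph, central = central)) {
  vm   <- partition_weighted_motion(total_speed(trc), tm, w)
  img  <- simulate_volume(ph, trc, tm, sim_config())$image
  rmse <- sqrt(mean((img[mask$mask] - ph$data[mask$mask])^2))
  cat(sprintf("M = %.2f mm   M_PW = %.2f mm   masked RMSE = %.4f\n",
              vm$M[1], vm$M_PW[1], rmse))
}
```

```
M = 9.95 mm   M_PW = 0.00 mm   masked RMSE = 0.0001   (peripheral)
M = 9.96 mm   M_PW = 49.55 mm   masked RMSE = 0.4999   (central)
```

The plain integrated motion `M` is blind to the difference — both bursts
score ~10 mm. The partition-weighted metric separates them by orders of
magnitude, and the simulated image error follows `M_PW`, not `M`: that
is the case for weighting motion by the k-space energy of the partition
being acquired.

At a larger scale (a simulated 100-volume uncorrected run with frequent
movement bursts of varying speed), the saturating-exponential fit of
per-volume RMSE against M_PW reaches r² ≈ 0.72 versus r² ≈ 0.66 for M,
and a full 2 × 3 factorial run shows no tSNR penalty from leaving the
correction on when the head is still, large tSNR gains when it moves,
and a percent-RMSE-reduction curve that rises with motion level — the
qualitative signature of a working PMC system.

## Package layout

| Area | Functions |
|---|---|
| Trace synthesis & logs | `motion_config`, `generate_trace`, `add_vibration`, `write_log`, `read_log` |
| Motion metrics | `lowpass`, `total_speed`, `acq_timing`, `integrated_motion`, `partition_weights`, `partition_weighted_motion` |
| Simulator | `make_phantom`, `apply_rigid`, `sim_config`, `simulate_volume`, `simulate_series`, `write_series`, `read_series` |
| Image quality | `discard_initial`, `realign`, `compute_tsnr`, `build_reference`, `make_mask`, `scale_and_rmse`, `quality_pipeline` |
| Artifact model | `fit_saturating`, `compare_predictors`, `binned_percent_reduction` |
| Experiment runner | `factorial_config`, `run_factorial`, `generate_fixtures` |

The methods vignette (`vignettes/epimotion-methods.Rmd`) documents the
models, their assumptions, parameter choices and known limitations.
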