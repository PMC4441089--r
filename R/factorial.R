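#' Configuration of the desk-scale factorial PMC experiment
#'
#' Describes a 2 (PMC on/off) x 3 (no/slow/fast motion) simulated
#' experiment mirroring the design of camera-based PMC validation studies.
#' Unlike a volunteer, the simulator can replay exactly the same motion
#' trace for the PMC-on and PMC-off members of a pair (they share the
#' regime seed), so motion levels match by construction.
#'
#' @param regimes Motion regimes to run (subset of none/slow/fast).
#' @param pmc_levels Logical vector of PMC settings (default off and on).
#' @param shape Phantom matrix size; the third axis is the partition
#'   direction and sets `partitions_per_volume`.
#' @param voxel_size Voxel size in mm (default 3, the low-resolution
#'   protocol analogue).
#' @param phantom_kind Passed to [make_phantom()].
#' @param n_volumes Image volumes per run (default 100).
#' @param tr Excitation repetition time in s (default 0.078).
#' @param noise_sd Image noise SD as a fraction of the mean intensity
#'   over the phantom support (default 0.02).
#' @param pmc_latency Latency of the prospective correction in s. The
#'   default of one camera frame (1/80 s) models the staleness of the
#'   pose available when the scanner updates the FOV immediately before
#'   each excitation, the residual error source of a real PMC system;
#'   set 0 for an idealised instantaneous correction.
#' @param discard Initial volumes discarded before quality metrics
#'   (default 5).
#' @param baseline_volumes Instructed-still volumes at the start of each
#'   run (default 12).
#' @param realign Rigidly realign each series to its first volume before
#'   quality metrics (default TRUE)?
#' @param mask_provenance Passed to [make_mask()].
#' @param seed Master seed; all per-cell seeds derive from it.
#' @return An object of class `factorial_config`.
#' @export
factorial_config <- function(regimes = c("none", "slow", "fast"),
                             pmc_levels = c(FALSE, TRUE),
                             shape = c(32, 32, 32), voxel_size = 3,
                             phantom_kind = "multi_ellipsoid",
                             n_volumes = 100, tr = 0.078,
                             noise_sd = 0.02, pmc_latency = 1 / 80,
                             discard = 5, baseline_volumes = 12,
                             realign = TRUE,
                             mask_provenance = "threshold_morphology",
                             seed = 1) {
  regimes <- match.arg(regimes, several.ok = TRUE)
  if (baseline_volumes <= discard)
    stop("baseline_volumes must exceed the number of discarded volumes")
  structure(as.list(environment()), class = "factorial_config")
}

#' Read a factorial configuration from a YAML file
#' @param path Path to a YAML file whose keys are arguments of
#'   [factorial_config()].
#' @export
read_factorial_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  do.call(factorial_config, yaml::read_yaml(path))
}

cell_seed <- function(seed, i) (as.integer(seed) * 7L + i * 1009L) %% 2147483629L

#' Full image-quality pipeline for one simulated run
#'
#' Applies the study's per-run analysis to a simulated series and its
#' motion trace: optional rigid realignment to the first volume, discard
#' of the initial volumes, partition weights from the mean of the
#' baseline (instructed-still) volumes, per-volume M and M_PW from the
#' 10 Hz low-passed trace, the M_PW-gated reference image, brain mask,
#' global mean-signal scaling with per-volume RMSE, and voxelwise tSNR.
#'
#' @param series A `recon_series` from [simulate_series()].
#' @param trace The raw motion trace used for the simulation.
#' @param discard Initial volumes to discard (default 5).
#' @param baseline_volumes Instructed-still volumes, in the original
#'   numbering (default 12); volumes `discard+1 .. baseline_volumes`
#'   form the baseline after discarding.
#' @param do_realign Realign before metrics (default TRUE)?
#' @param mask_provenance,phantom Mask construction; if
#'   `mask_provenance = "phantom_support"` the phantom must be supplied.
#' @param weights Optional [partition_weights()] to use instead of
#'   deriving them from the baseline volumes of this series.
#' @return List with `vm` (per-volume M/M_PW for the retained volumes),
#'   `rmse` (per-volume RMSE), `mean_tsnr`, `tsnr_map`, `weights`,
#'   `reference`, `mask`, `scale` and `realign_poses`.
#' @export
quality_pipeline <- function(series, trace, discard = 5,
                             baseline_volumes = 12, do_realign = TRUE,
                             mask_provenance = "threshold_morphology",
                             phantom = NULL, weights = NULL) {
  timing_full <- series$timing
  realign_poses <- NULL
  if (do_realign) {
    ra <- realign(series)
    series <- ra$series
    realign_poses <- ra$poses
  }
  series_t <- discard_initial(series, discard)
  baseline_idx <- seq_len(baseline_volumes - discard)
  d3 <- dim(series_t$data)[1:3]
  if (is.null(weights)) {
    wsrc <- array(rowMeans(matrix(series_t$data[, , , baseline_idx,
                                                drop = FALSE],
                                  prod(d3), length(baseline_idx))), d3)
    weights <- partition_weights(wsrc, partition_axis = 3)
  }
  w <- weights
  speed <- total_speed(lowpass(trace, 10))
  vm <- partition_weighted_motion(speed, timing_full, w)
  vm_t <- vm[vm$volume_index > discard, , drop = FALSE]
  refo <- build_reference(series_t, vm_t$M_PW, baseline_idx)
  mask <- if (mask_provenance == "phantom_support") {
    make_mask(phantom, provenance = "phantom_support")
  } else make_mask(refo$reference, provenance = "threshold_morphology")
  qr <- scale_and_rmse(series_t, refo$reference, mask)
  tsnr_map <- compute_tsnr(series_t)
  list(vm = vm_t, rmse = qr$rmse, mean_tsnr = mean_tsnr(tsnr_map, mask),
       tsnr_map = tsnr_map, weights = w, reference = refo, mask = mask,
       scale = qr$scale, realign_poses = realign_poses)
}

#' Run the desk-scale factorial PMC experiment
#'
#' For every motion regime, generates one trace (shared between the
#' PMC-on and PMC-off runs of the pair), simulates the 3D EPI series for
#' each PMC setting, applies [quality_pipeline()], and summarises mean
#' in-mask tSNR and mean M_PW per cell. For regimes with motion it also
#' fits the saturating-exponential artifact model to the PMC-off run with
#' both M and M_PW as predictors and computes the binned percent RMSE
#' reduction of PMC on vs off. Fully reproducible from the master seed.
#'
#' @param config A [factorial_config()].
#' @param verbose Print per-cell progress (default FALSE)?
#' @return List with `summary` (one row per cell: regime, pmc,
#'   mean_tsnr, mean_M, mean_MPW, sd_MPW), `cells` (named list of
#'   pipeline results), `fits` (per motion regime, the M vs M_PW
#'   comparison on the PMC-off run) and `reduction` (per motion regime, a
#'   `binned_summary`).
#' @export
run_factorial <- function(config, verbose = FALSE) {
  if (!inherits(config, "factorial_config"))
    stop("config must be created by factorial_config()")
  phantom <- make_phantom(config$shape, config$phantom_kind,
                          voxel_size = config$voxel_size,
                          seed = cell_seed(config$seed, 0L))
  P <- config$shape[3]
  timing <- acq_timing(config$n_volumes, tr = config$tr,
                       partitions_per_volume = P)
  summary_rows <- list()
  cells <- list()
  fits <- list()
  reduction <- list()
  for (ri in seq_along(config$regimes)) {
    regime <- config$regimes[ri]
    tcfg <- motion_config(regime,
                          duration = config$n_volumes *
                            timing$volume_duration + 1,
                          volume_duration = timing$volume_duration,
                          baseline_still_volumes = config$baseline_volumes,
                          seed = cell_seed(config$seed, ri))
    trace <- generate_trace(tcfg)
    pair_weights <- NULL
    for (pmc in config$pmc_levels) {
      scfg <- sim_config(pmc = pmc,
                         pmc_latency = if (pmc) config$pmc_latency else 0,
                         noise_sd = config$noise_sd,
                         seed = cell_seed(config$seed, 100L + ri))
      series <- simulate_series(phantom, trace, timing, scfg)
      # the first member of each pair derives the partition weights from
      # its own baseline; the pair shares them so that the paired-by-seed
      # design yields exactly matching M_PW distributions
      qp <- quality_pipeline(series, trace, discard = config$discard,
                             baseline_volumes = config$baseline_volumes,
                             do_realign = config$realign,
                             mask_provenance = config$mask_provenance,
                             phantom = phantom, weights = pair_weights)
      if (is.null(pair_weights)) pair_weights <- qp$weights
      key <- paste0(regime, "_pmc_", if (pmc) "on" else "off")
      qp$tsnr_map <- NULL  # keep the result object light
      cells[[key]] <- qp
      summary_rows[[key]] <- data.frame(
        regime = regime, pmc = if (pmc) "on" else "off",
        mean_tsnr = qp$mean_tsnr, mean_M = mean(qp$vm$M),
        mean_MPW = mean(qp$vm$M_PW), sd_MPW = stats::sd(qp$vm$M_PW))
      if (verbose)
        message(key, ": tSNR ", signif(qp$mean_tsnr, 4), ", M_PW ",
                signif(mean(qp$vm$M_PW), 4))
    }
    if (regime != "none" && all(c(TRUE, FALSE) %in% config$pmc_levels)) {
      off <- cells[[paste0(regime, "_pmc_off")]]
      on <- cells[[paste0(regime, "_pmc_on")]]
      fits[[regime]] <- compare_predictors(off$vm$M, off$vm$M_PW,
                                           off$rmse$rmse)
      reduction[[regime]] <- binned_percent_reduction(
        off$vm$M_PW, off$rmse$rmse, on$vm$M_PW, on$rmse$rmse)
    }
  }
  list(summary = do.call(rbind, c(summary_rows,
                                  list(make.row.names = FALSE))),
       cells = cells, fits = fits, reduction = reduction,
       phantom = phantom, timing = timing)
}

#' Generate a small bundled fixture data set
#'
#' Writes, under `dir`: a digital phantom (`phantom.nii.gz`), a 30 s
#' motion trace per regime (`trace_<regime>.tsv`, baseline shortened to
#' two volumes so bursts fit in 30 s) and a 10-volume simulated series
#' with its ground-truth pose log (`series.nii.gz`, `poses.tsv`).
#' Regenerates identically for a fixed seed.
#'
#' @param seed Integer seed.
#' @param dir Output directory (default a fresh temporary directory).
#' @return Named character vector of the written paths.
#' @export
generate_fixtures <- function(seed = 1, dir = tempfile("epimotion_fix")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  phantom <- make_phantom(c(32, 32, 32), "multi_ellipsoid", voxel_size = 3,
                          seed = seed)
  timing <- acq_timing(10, partitions_per_volume = 32)
  paths <- c(phantom = file.path(dir, "phantom.nii.gz"))
  write_series(array(phantom$data, c(dim(phantom$data), 1)),
               paths["phantom"], voxel_size = phantom$voxel_size)
  for (regime in c("none", "slow", "fast")) {
    cfg <- motion_config(regime, duration = 30,
                         volume_duration = timing$volume_duration,
                         baseline_still_volumes = 2, seed = seed)
    p <- file.path(dir, paste0("trace_", regime, ".tsv"))
    write_log(generate_trace(cfg), p)
    paths[paste0("trace_", regime)] <- p
  }
  trace <- read_log(paths["trace_fast"])
  series <- simulate_series(phantom, trace, timing,
                            sim_config(noise_sd = 0.02, seed = seed))
  paths["series"] <- file.path(dir, "series.nii.gz")
  write_series(series, paths["series"])
  paths["poses"] <- file.path(dir, "poses.tsv")
  utils::write.table(series$poses, paths["poses"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}
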