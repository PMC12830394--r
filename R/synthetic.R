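METAVIR_STAGES <- c("F0", "F1", "F2", "F3", "F4")

# Published MRE per-stage stiffness (kPa): mean, SD. Also the staging
# reference used by stage_threshold_table().
MRE_STAGE_STIFFNESS <- data.frame(
  stage = METAVIR_STAGES,
  mean_kpa = c(2.13, 2.49, 2.83, 3.60, 5.20),
  sd_kpa   = c(0.27, 0.28, 0.32, 0.81, 1.02)
)

# 2D shear-wave elastography per-stage stiffness (kPa), all-etiology cohort.
USE_STAGE_PARAMS <- data.frame(
  stage = METAVIR_STAGES,
  mean_kpa = c(6.00, 8.74, 10.74, 13.68, 18.05),
  sd_kpa   = c(4.11, 4.18, 3.57, 4.18, 4.84)
)

KPA_FLOOR <- 0.1  # positive floor for truncated stiffness draws

#' Simulation configuration for phantoms and cohorts
#'
#' Defines the generating conditions for the synthetic study: a 49-patient
#' cohort with METAVIR stage counts 8/16/6/12/7 (F0..F4), ~67% hepatitis-B
#' etiology, per-stage true stiffness drawn from the published MRE stage
#' distributions, two virtual-elastography readers differing by independent
#' Gaussian noise (SD 0.21 kPa, chosen so inter-reader ICC sits near 0.97),
#' and two shear-wave ultrasound acquisitions per patient drawn from the
#' published per-stage ultrasound distributions. Phantoms are single-organ
#' blocks imaged at b = 200/1500 s/mm^2 with Rician magnitude noise at
#' SNR = s0/sigma (default 30).
#'
#' @param seed Integer master seed; fans out to per-component substreams.
#' @param grid_shape Length-3 positive integers, phantom grid in voxels.
#' @param voxel_size_mm Length-3 positive reals (mm).
#' @param s0 Baseline low-b signal (arbitrary units, > 0).
#' @param snr Signal-to-noise ratio `s0 / sigma_Rician`; `Inf` disables noise.
#' @param stage_counts Named integer vector F0..F4 of patients per stage.
#' @param hbv_fraction Fraction of the cohort with HBV etiology, in `[0, 1]`.
#' @param reader_sd_kpa SD (kPa) of each reader's independent measurement
#'   noise around the patient's true stiffness.
#' @param use_params Data frame `stage, mean_kpa, sd_kpa` for the ultrasound
#'   generating distributions.
#' @param stage_stiffness Data frame `stage, mean_kpa, sd_kpa` for the true
#'   (MRE-scale) stiffness distributions.
#' @return An object of class `vmre_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              grid_shape = c(32L, 32L, 32L),
                              voxel_size_mm = c(4, 4, 6),
                              s0 = 1000,
                              snr = 30,
                              stage_counts = c(F0 = 8L, F1 = 16L, F2 = 6L,
                                               F3 = 12L, F4 = 7L),
                              hbv_fraction = 0.67,
                              reader_sd_kpa = 0.21,
                              use_params = USE_STAGE_PARAMS,
                              stage_stiffness = MRE_STAGE_STIFFNESS) {
  if (!is.numeric(s0) || s0 <= 0) stop("s0 must be > 0", call. = FALSE)
  if (!is.numeric(snr) || is.na(snr) || snr <= 0)
    stop("snr must be > 0 (use Inf to disable noise)", call. = FALSE)
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stop("grid_shape must be 3 positive integers", call. = FALSE)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive reals", call. = FALSE)
  if (!all(METAVIR_STAGES %in% names(stage_counts)))
    stop("stage_counts must name all of F0..F4", call. = FALSE)
  stage_counts <- as.integer(stage_counts[METAVIR_STAGES])
  names(stage_counts) <- METAVIR_STAGES
  if (any(stage_counts < 0) || sum(stage_counts) == 0)
    stop("stage_counts must be non-negative and sum to a positive cohort size",
         call. = FALSE)
  if (hbv_fraction < 0 || hbv_fraction > 1)
    stop("hbv_fraction must lie in [0, 1]", call. = FALSE)
  if (reader_sd_kpa < 0) stop("reader_sd_kpa must be >= 0", call. = FALSE)
  for (tab in list(use_params, stage_stiffness)) {
    stopifnot(all(c("stage", "mean_kpa", "sd_kpa") %in% names(tab)),
              all(METAVIR_STAGES %in% tab$stage), all(tab$sd_kpa >= 0))
  }
  structure(list(seed = as.integer(seed), grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm), s0 = s0, snr = snr,
                 stage_counts = stage_counts, hbv_fraction = hbv_fraction,
                 reader_sd_kpa = reader_sd_kpa, use_params = use_params,
                 stage_stiffness = stage_stiffness),
            class = "vmre_sim_config")
}

stage_row <- function(tab, stage) tab[match(stage, tab$stage), ]

#' Generate a single-stage DWI phantom
#'
#' Builds a block phantom whose organ voxels carry a true stiffness field
#' drawn from the stage's (mean, SD), floored at 0.1 kPa. The implied
#' shifted-ADC field is the exact inverse of the stiffness calibration,
#' `sADC = (beta - stiffness) / (-alpha)`; voxels where that is non-positive
#' (stiffness >= beta, nonphysical under the linear calibration) are removed
#' from the label volume. Noiseless signals are `S_low = s0` and
#' `S_high = s0 * exp(-(b_high - b_low) * sADC)` with sADC in mm^2/s; Rician
#' magnitude noise `sqrt((S + n1)^2 + n2^2)` with
#' `n1, n2 ~ N(0, (s0/snr)^2)` is applied to both channels unless
#' `snr = Inf`.
#'
#' @param config A [simulation_config()].
#' @param stage One of `"F0".."F4"`.
#' @param calib A [calibration_params()].
#' @param out_prefix Optional path prefix; when given, the two channels are
#'   written as `<prefix>_b200.nii.gz` / `<prefix>_b1500.nii.gz` (plus
#'   `_label` and `_truth` volumes) sharing one affine.
#' @return A list with elements `dwi` ([dwi_series()]), `label` (integer
#'   array, 1 = labeled organ voxel), `stiffness` (true kPa field), `stage`,
#'   and `files` (paths, when written).
#' @export
generate_phantom <- function(config, stage, calib = calibration_params(),
                             out_prefix = NULL) {
  stopifnot(inherits(config, "vmre_sim_config"))
  stage <- match.arg(stage, METAVIR_STAGES)
  row <- stage_row(config$stage_stiffness, stage)
  dims <- config$grid_shape
  # organ: central block with a margin of 1/8 of each dimension (min 1 voxel)
  margin <- pmax(1L, dims %/% 8L)
  organ <- array(FALSE, dims)
  organ[(margin[1] + 1):(dims[1] - margin[1]),
        (margin[2] + 1):(dims[2] - margin[2]),
        (margin[3] + 1):(dims[3] - margin[3])] <- TRUE

  sd_seed <- substream(config$seed, "phantom", match(stage, METAVIR_STAGES))
  res <- with_seed(sd_seed, {
    stiff <- array(0, dims)
    stiff[organ] <- pmax(stats::rnorm(sum(organ), row$mean_kpa, row$sd_kpa),
                         KPA_FLOOR)
    sadc <- (calib$beta - stiff) / (-calib$alpha)     # 1e-3 mm^2/s
    label <- organ & sadc > 0
    s_lo <- array(0, dims); s_hi <- array(0, dims)
    s_lo[organ] <- config$s0
    s_hi[organ] <- config$s0 * exp(-1300 * sadc[organ] * 1e-3)
    if (is.finite(config$snr)) {
      sigma <- config$s0 / config$snr
      n <- prod(dims)
      s_lo <- sqrt((s_lo + array(stats::rnorm(n, 0, sigma), dims))^2 +
                     array(stats::rnorm(n, 0, sigma), dims)^2)
      s_hi <- sqrt((s_hi + array(stats::rnorm(n, 0, sigma), dims))^2 +
                     array(stats::rnorm(n, 0, sigma), dims)^2)
    }
    list(stiff = stiff, label = label, s_lo = s_lo, s_hi = s_hi)
  })

  dwi <- dwi_series(res$s_lo, res$s_hi, b_low = 200, b_high = 1500,
                    voxel_size_mm = config$voxel_size_mm)
  out <- list(dwi = dwi, label = array(as.integer(res$label), dims),
              stiffness = res$stiff, stage = stage, files = NULL)
  if (!is.null(out_prefix)) {
    files <- c(b200 = paste0(out_prefix, "_b200.nii.gz"),
               b1500 = paste0(out_prefix, "_b1500.nii.gz"),
               label = paste0(out_prefix, "_label.nii.gz"),
               truth = paste0(out_prefix, "_truth.nii.gz"))
    write_volume_nifti(res$s_lo, files["b200"], config$voxel_size_mm)
    write_volume_nifti(res$s_hi, files["b1500"], config$voxel_size_mm)
    write_volume_nifti(out$label, files["label"], config$voxel_size_mm)
    write_volume_nifti(res$stiff, files["truth"], config$voxel_size_mm)
    out$files <- files
  }
  out
}

#' Generate a synthetic patient cohort
#'
#' One record per patient honoring the configured stage counts. Each
#' patient's true stiffness is drawn from the stage's MRE distribution
#' (floored at 0.1 kPa); the two reader measurements add independent
#' `N(0, reader_sd_kpa^2)` noise to the truth; the two ultrasound
#' acquisitions are independent draws from the stage's ultrasound
#' distribution (floored positive). Etiology assigns
#' `round(n * hbv_fraction)` patients to HBV at random, the remainder split
#' between MASLD and other chronic liver disease.
#'
#' @param config A [simulation_config()].
#' @return A data frame of class `vmre_cohort` with columns `id`, `stage`
#'   (ordered factor F0..F4), `etiology`, `vmre_r1`, `vmre_r2`, `use_a1`,
#'   `use_a2`, `truth`; attribute `provenance = "simulated"`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "vmre_sim_config"))
  counts <- config$stage_counts
  n <- sum(counts)
  stage <- rep(METAVIR_STAGES, counts)
  s_mu <- config$stage_stiffness$mean_kpa[match(stage, config$stage_stiffness$stage)]
  s_sd <- config$stage_stiffness$sd_kpa[match(stage, config$stage_stiffness$stage)]
  u_mu <- config$use_params$mean_kpa[match(stage, config$use_params$stage)]
  u_sd <- config$use_params$sd_kpa[match(stage, config$use_params$stage)]

  truth <- with_seed(substream(config$seed, "truth"),
                     pmax(stats::rnorm(n, s_mu, s_sd), KPA_FLOOR))
  readers <- with_seed(substream(config$seed, "readers"), {
    cbind(pmax(truth + stats::rnorm(n, 0, config$reader_sd_kpa), KPA_FLOOR),
          pmax(truth + stats::rnorm(n, 0, config$reader_sd_kpa), KPA_FLOOR))
  })
  use <- with_seed(substream(config$seed, "use"), {
    cbind(pmax(stats::rnorm(n, u_mu, u_sd), KPA_FLOOR),
          pmax(stats::rnorm(n, u_mu, u_sd), KPA_FLOOR))
  })
  etiology <- with_seed(substream(config$seed, "etiology"), {
    e <- rep("other", n)
    n_hbv <- round(n * config$hbv_fraction)
    hbv_idx <- sample.int(n, n_hbv)
    e[hbv_idx] <- "HBV"
    rest <- setdiff(seq_len(n), hbv_idx)
    e[rest] <- sample(c("MASLD", "other"), length(rest), replace = TRUE)
    e
  })

  cohort <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    stage = factor(stage, levels = METAVIR_STAGES, ordered = TRUE),
    etiology = etiology,
    vmre_r1 = readers[, 1], vmre_r2 = readers[, 2],
    use_a1 = use[, 1], use_a2 = use[, 2],
    truth = truth,
    stringsAsFactors = FALSE
  )
  attr(cohort, "provenance") <- "simulated"
  class(cohort) <- c("vmre_cohort", "data.frame")
  cohort
}

#' Write / read a cohort table as CSV
#'
#' Columns `id,stage,etiology,vmre_r1,vmre_r2,use_a1,use_a2,truth`; floats
#' serialized at full precision (>= 6 significant digits).
#'
#' @param cohort A `vmre_cohort` data frame.
#' @param path CSV file path.
#' @return `path` (write) or the cohort (read), invisibly for the writer.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "stage", "etiology", "vmre_r1", "vmre_r2", "use_a1", "use_a2")
  if (!all(need %in% names(df)))
    stop("cohort CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df$stage <- factor(df$stage, levels = METAVIR_STAGES, ordered = TRUE)
  if (anyDuplicated(df$id)) stop("cohort ids must be unique", call. = FALSE)
  attr(df, "provenance") <- "imported"
  class(df) <- c("vmre_cohort", "data.frame")
  df
}
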