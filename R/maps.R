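#' Calibration constants linking shifted ADC to virtual stiffness
#'
#' The virtual MR elastography (VMRE) conversion is the affine map
#' \eqn{VMRE (kPa) = \alpha \cdot sADC + \beta}, with sADC expressed in
#' units of 1e-3 mm^2/s. The defaults (\eqn{\alpha = -12.740} kPa per
#' 1e-3 mm^2/s, \eqn{\beta = 14.0} kPa) are the published calibration
#' against conventional MR elastography; \eqn{\alpha} must be negative
#' because tissue stiffness decreases with diffusivity.
#'
#' @param alpha Slope in kPa per 1e-3 mm^2/s; must be strictly negative.
#' @param beta Intercept in kPa.
#' @return An object of class `vmre_calibration`.
#' @examples
#' cal <- calibration_params()
#' cal$alpha * 0.69 + cal$beta  # 5.21 kPa to two decimals
#' @export
calibration_params <- function(alpha = -12.740, beta = 14.0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("alpha must be a single finite number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop("beta must be a single finite number", call. = FALSE)
  if (alpha >= 0)
    stop("degenerate calibration: alpha must be negative (stiffness decreases with diffusivity)",
         call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "vmre_calibration")
}

#' Paired b-value diffusion-weighted series
#'
#' Container for two co-registered magnitude volumes acquired at a low and a
#' high diffusion weighting (defaults 200 and 1500 s/mm^2).
#'
#' @param signal_low_b,signal_high_b 3-D non-negative arrays of equal shape
#'   (arbitrary signal units).
#' @param b_low,b_high b-values in s/mm^2; `b_high > b_low > 0`.
#' @param voxel_size_mm Length-3 positive voxel dimensions.
#' @param affine Optional 4x4 voxel-to-mm transform; defaults to a diagonal
#'   RAS affine built from `voxel_size_mm`.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(signal_low_b, signal_high_b, b_low = 200, b_high = 1500,
                       voxel_size_mm = c(1, 1, 1), affine = NULL) {
  signal_low_b <- as.array(signal_low_b)
  signal_high_b <- as.array(signal_high_b)
  if (length(dim(signal_low_b)) != 3L || length(dim(signal_high_b)) != 3L)
    stop("signal volumes must be 3-D arrays", call. = FALSE)
  if (!identical(dim(signal_low_b), dim(signal_high_b)))
    stop("signal volumes must share one shape", call. = FALSE)
  if (any(signal_low_b < 0, na.rm = TRUE) || any(signal_high_b < 0, na.rm = TRUE))
    stop("magnitude signals must be non-negative", call. = FALSE)
  if (!(b_high > b_low && b_low > 0))
    stop("require b_high > b_low > 0", call. = FALSE)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive reals", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  structure(list(signal_low_b = signal_low_b, signal_high_b = signal_high_b,
                 b_low = b_low, b_high = b_high,
                 voxel_size_mm = as.numeric(voxel_size_mm), affine = affine),
            class = "dwi_series")
}

new_parametric_map <- function(values, unit, valid_mask, affine, voxel_size_mm,
                               physical_mask = NULL) {
  stopifnot(unit %in% c("sadc_e3_mm2_per_s", "kPa"))
  structure(list(values = values, unit = unit, valid_mask = valid_mask,
                 physical_mask = physical_mask %||% valid_mask,
                 affine = affine, voxel_size_mm = voxel_size_mm),
            class = "parametric_map")
}

#' Compute a shifted-ADC map from a paired b-value series
#'
#' Voxelwise \eqn{sADC = ln(S_{low}/S_{high}) / (b_{high} - b_{low})},
#' reported in 1e-3 mm^2/s. Voxels where either signal is non-positive are
#' masked invalid (no clamping: log of zero is never taken). Negative sADC
#' values — possible when noise inverts the decay — are retained in `values`
#' and in `valid_mask` but excluded from the secondary `physical_mask`.
#'
#' @param dwi A [dwi_series()].
#' @return A `parametric_map` with unit `"sadc_e3_mm2_per_s"`.
#' @export
compute_sadc_map <- function(dwi) {
  if (!inherits(dwi, "dwi_series")) stop("dwi must be a dwi_series", call. = FALSE)
  s_lo <- dwi$signal_low_b
  s_hi <- dwi$signal_high_b
  valid <- is.finite(s_lo) & is.finite(s_hi) & s_lo > 0 & s_hi > 0
  vals <- array(NA_real_, dim(s_lo))
  # sADC in mm^2/s, then scaled to the 1e-3 mm^2/s reporting unit
  vals[valid] <- log(s_lo[valid] / s_hi[valid]) / (dwi$b_high - dwi$b_low) * 1e3
  new_parametric_map(vals, "sadc_e3_mm2_per_s", valid,
                     dwi$affine, dwi$voxel_size_mm,
                     physical_mask = valid & !is.na(vals) & vals > 0)
}

#' Convert a shifted-ADC map to a virtual stiffness map
#'
#' Applies \eqn{VMRE = \alpha \cdot sADC + \beta} voxelwise, with sADC on the
#' 1e-3 mm^2/s scale. Masks are propagated unchanged.
#'
#' @param map A `parametric_map` with unit `"sadc_e3_mm2_per_s"`.
#' @param calib A [calibration_params()].
#' @return A `parametric_map` in kPa.
#' @export
sadc_to_vmre <- function(map, calib = calibration_params()) {
  check_map(map, "sadc_e3_mm2_per_s")
  out <- map
  out$values <- calib$alpha * map$values + calib$beta
  out$unit <- "kPa"
  out
}

#' Invert a virtual stiffness map back to shifted ADC
#'
#' Exact inverse of [sadc_to_vmre()]: \eqn{sADC = (VMRE - \beta)/\alpha}.
#' Used by the phantom generator to derive the diffusivity field that a
#' target stiffness implies.
#'
#' @inheritParams sadc_to_vmre
#' @param map A `parametric_map` in kPa.
#' @return A `parametric_map` with unit `"sadc_e3_mm2_per_s"`.
#' @export
vmre_to_sadc <- function(map, calib = calibration_params()) {
  check_map(map, "kPa")
  out <- map
  out$values <- (map$values - calib$beta) / calib$alpha
  out$unit <- "sadc_e3_mm2_per_s"
  out
}

check_map <- function(map, unit) {
  if (!inherits(map, "parametric_map"))
    stop("expected a parametric_map", call. = FALSE)
  if (!identical(map$unit, unit))
    stop(sprintf("unit error: expected a map in %s, got %s", unit, map$unit),
         call. = FALSE)
  invisible(map)
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %s, %s, %d/%d valid voxels\n",
              paste(dim(x$values), collapse = "x"), x$unit,
              sum(x$valid_mask), length(x$valid_mask)))
  v <- x$values[x$valid_mask]
  if (length(v))
    cat(sprintf("  range %.4g .. %.4g, median %.4g\n",
                min(v), max(v), stats::median(v)))
  invisible(x)
}

#' Export map slices as color raster images
#'
#' Deterministic per-voxel color assignment: values are clamped to
#' `range` and mapped linearly onto the palette; invalid voxels are
#' rendered as the background color. One PNG per requested slice.
#'
#' @param map A `parametric_map`.
#' @param range Length-2 `(lo, hi)` display window, `lo < hi`.
#' @param palette Name accepted by [grDevices::hcl.colors()] (default
#'   `"Inferno"`).
#' @param out_prefix Path prefix; files are written as
#'   `<out_prefix>_z<slice>.png`.
#' @param slices Integer slice indices (default: all slices).
#' @param background Background RGB for invalid voxels, in `[0, 1]`.
#' @return Invisibly, the written file paths.
#' @export
export_color_map <- function(map, range, palette = "Inferno",
                             out_prefix, slices = NULL,
                             background = c(0, 0, 0)) {
  stopifnot(inherits(map, "parametric_map"))
  lo <- range[1]; hi <- range[2]
  if (!(lo < hi)) stop("range must satisfy lo < hi", call. = FALSE)
  if (!any(map$valid_mask))
    warning("empty valid mask: exporting background-only images")
  cols <- grDevices::hcl.colors(256L, palette)
  rgb_tab <- t(grDevices::col2rgb(cols)) / 255
  dims <- dim(map$values)
  slices <- slices %||% seq_len(dims[3])
  paths <- character(0)
  for (z in slices) {
    sl <- map$values[, , z]
    ok <- map$valid_mask[, , z] & is.finite(sl)
    idx <- pmin(pmax((sl - lo) / (hi - lo), 0), 1)       # clamp to window
    ci <- 1L + as.integer(round(idx * 255))
    img <- array(rep(background, each = prod(dims[1:2])),
                 dim = c(dims[1], dims[2], 3))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[ok] <- rgb_tab[ci[ok], ch]
      img[, , ch] <- plane
    }
    # image rows run top-to-bottom; volume y runs bottom-to-top
    img <- aperm(img[, rev(seq_len(dims[2])), , drop = FALSE], c(2, 1, 3))
    path <- sprintf("%s_z%03d.png", out_prefix, z)
    png::writePNG(img, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a paired b-value series from two NIfTI files
#'
#' @param path_low_b,path_high_b NIfTI files holding the low- and high-b
#'   magnitude volumes; must share geometry.
#' @inheritParams dwi_series
#' @return A [dwi_series()].
#' @export
read_dwi_nifti <- function(path_low_b, path_high_b, b_low = 200, b_high = 1500) {
  lo <- RNifti::readNifti(path_low_b)
  hi <- RNifti::readNifti(path_high_b)
  dwi_series(as.array(lo), as.array(hi), b_low = b_low, b_high = b_high,
             voxel_size_mm = RNifti::pixdim(lo)[1:3],
             affine = unclass(RNifti::xform(lo)))
}

#' Write a volume (array or parametric map) to NIfTI
#'
#' @param x A 3-D array or a `parametric_map`.
#' @param path Output file path (`.nii` / `.nii.gz`).
#' @param voxel_size_mm Voxel dimensions, used when `x` is a bare array.
#' @return Invisibly, `path`.
#' @export
write_volume_nifti <- function(x, path, voxel_size_mm = c(1, 1, 1)) {
  if (inherits(x, "parametric_map")) {
    voxel_size_mm <- x$voxel_size_mm
    x <- x$values
  }
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
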