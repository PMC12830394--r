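#' Region-of-interest set
#'
#' A collection of per-slice ROIs, each either an explicit in-plane boolean
#' mask (`list(slice=, mask=)`) or a circle spec in mm
#' (`list(slice=, cx_mm=, cy_mm=, diameter_mm=)`). VMRE measurement protocol
#' requires ROIs spanning at least three consecutive slices; ultrasound
#' (USE) circles default to 10 mm diameter.
#'
#' @param rois List of ROI specs as above.
#' @param modality `"VMRE"` or `"USE"`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(rois, modality = c("VMRE", "USE")) {
  modality <- match.arg(modality)
  if (!length(rois)) stop("roi set must be non-empty", call. = FALSE)
  rois <- lapply(rois, function(r) {
    if (is.null(r$slice)) stop("each ROI needs a slice index", call. = FALSE)
    if (!is.null(r$mask)) {
      if (!any(r$mask)) stop("ROI masks must be non-empty", call. = FALSE)
    } else {
      if (is.null(r$cx_mm) || is.null(r$cy_mm))
        stop("circle ROIs need cx_mm and cy_mm", call. = FALSE)
      r$diameter_mm <- r$diameter_mm %||% if (modality == "USE") 10 else
        stop("VMRE circle ROIs need an explicit diameter_mm", call. = FALSE)
      if (r$diameter_mm <= 0) stop("diameter must be positive", call. = FALSE)
    }
    r
  })
  structure(list(rois = rois, modality = modality), class = "roi_set")
}

# Longest run of consecutive integers among the ROI slices.
max_consecutive_run <- function(slices) {
  s <- sort(unique(as.integer(slices)))
  if (!length(s)) return(0L)
  grp <- cumsum(c(1L, diff(s) != 1L))
  max(tabulate(grp))
}

# Rasterize a circle spec on the in-plane grid: a voxel belongs to the ROI
# iff its center lies within the circle (boundary included).
rasterize_circle <- function(roi, dims, voxel_size_mm) {
  cx <- (seq_len(dims[1]) - 0.5) * voxel_size_mm[1]
  cy <- (seq_len(dims[2]) - 0.5) * voxel_size_mm[2]
  r2 <- (roi$diameter_mm / 2)^2
  outer((cx - roi$cx_mm)^2, (cy - roi$cy_mm)^2, "+") <= r2
}

roi_mask <- function(roi, dims, voxel_size_mm) {
  if (!is.null(roi$mask)) {
    m <- roi$mask
    if (!identical(dim(m), dims[1:2]))
      stop("ROI mask shape does not match the map's in-plane shape",
           call. = FALSE)
    m
  } else {
    rasterize_circle(roi, dims, voxel_size_mm)
  }
}

#' Summarize a parametric map over an ROI set
#'
#' Computes the chosen statistic over the valid voxels of each ROI, then the
#' same statistic across per-ROI values (per-patient summary =
#' statistic-of-ROI-statistics, the protocol's reading). ROIs containing no
#' valid voxels are dropped with a warning. VMRE ROI sets must span at least
#' three consecutive slices. For USE sets the IQR/median quality flag is
#' attached automatically when there are at least two per-ROI values.
#'
#' @param map A `parametric_map` (typically in kPa).
#' @param rois A [roi_set()].
#' @param stat `"mean"` (default, the reading protocol) or `"median"`.
#' @param patient_id Identifier carried into the output.
#' @return A list of class `measurement_set`: `patient_id`, `modality`,
#'   `per_roi_values`, `summary`, `qc_ratio`, `qc_pass`.
#' @export
summarize_map_over_rois <- function(map, rois, stat = c("mean", "median"),
                                    patient_id = "") {
  stopifnot(inherits(map, "parametric_map"), inherits(rois, "roi_set"))
  stat <- match.arg(stat)
  dims <- dim(map$values)
  slices <- vapply(rois$rois, `[[`, numeric(1), "slice")
  if (any(slices < 1 | slices > dims[3]))
    stop("ROI slice index outside the volume", call. = FALSE)
  if (rois$modality == "VMRE" && max_consecutive_run(slices) < 3L)
    stop("VMRE ROI sets must span at least 3 consecutive slices",
         call. = FALSE)
  f <- if (stat == "mean") mean else stats::median
  per_roi <- vapply(rois$rois, function(r) {
    m <- roi_mask(r, dims, map$voxel_size_mm)
    vals <- map$values[, , r$slice][m & map$valid_mask[, , r$slice]]
    if (!length(vals)) NA_real_ else f(vals)
  }, numeric(1))
  if (anyNA(per_roi)) {
    warning(sprintf("%d ROI(s) had no valid voxels and were dropped",
                    sum(is.na(per_roi))))
    per_roi <- per_roi[!is.na(per_roi)]
  }
  if (!length(per_roi))
    stop("measurement error: all ROIs empty over the valid mask",
         call. = FALSE)
  qc_ratio <- NA_real_; qc_pass <- NA
  if (rois$modality == "USE" && length(per_roi) >= 2) {
    qc <- qc_iqr_median(per_roi)
    qc_ratio <- qc$ratio; qc_pass <- qc$pass
  }
  structure(list(patient_id = patient_id, modality = rois$modality,
                 per_roi_values = unname(per_roi), summary = f(per_roi),
                 qc_ratio = qc_ratio, qc_pass = qc_pass),
            class = "measurement_set")
}

#' Combine the two readers' stiffness measurements
#'
#' Per-patient VMRE value used for analysis: the arithmetic mean of the two
#' blinded readers. Vectorized; symmetric; idempotent on equal inputs.
#'
#' @param r1,r2 Positive stiffness values (kPa).
#' @return Mean stiffness (kPa).
#' @export
combine_readers <- function(r1, r2) {
  if (any(!is.finite(r1)) || any(!is.finite(r2)) || any(r1 <= 0) || any(r2 <= 0))
    stop("reader values must be positive", call. = FALSE)
  (r1 + r2) / 2
}

#' Combine two ultrasound acquisitions
#'
#' Each acquisition contributes the mean of its two ROIs; the final value is
#' the mean of the two acquisition means (equal weighting, so it equals the
#' grand mean of the four ROI values).
#'
#' @param acq1,acq2 Numeric vectors of per-ROI stiffness (kPa), typically
#'   length 2, all positive.
#' @return Final stiffness (kPa).
#' @export
combine_use_acquisitions <- function(acq1, acq2) {
  if (!length(acq1) || !length(acq2) || anyNA(acq1) || anyNA(acq2))
    stop("both acquisitions must be present and complete", call. = FALSE)
  if (any(acq1 <= 0) || any(acq2 <= 0))
    stop("stiffness values must be positive", call. = FALSE)
  mean(c(mean(acq1), mean(acq2)))
}

#' Elastography measurement quality: IQR/median ratio
#'
#' International elastography guideline criterion: a measurement set passes
#' when the interquartile-range-to-median ratio is at most 30% (boundary
#' inclusive). Quartiles use the linear-interpolation convention
#' ([stats::quantile()] type 7).
#'
#' @param values At least two stiffness values (kPa), median > 0.
#' @return List `ratio`, `pass`.
#' @export
qc_iqr_median <- function(values) {
  if (length(values) < 2) stop("need at least 2 values for QC", call. = FALSE)
  med <- stats::median(values)
  if (!is.finite(med) || med <= 0)
    stop("QC error: median must be positive", call. = FALSE)
  ratio <- stats::IQR(values, type = 7) / med
  list(ratio = ratio, pass = ratio <= 0.30)
}
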