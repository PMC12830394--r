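test_that("sADC map computes the log-ratio diffusivity and masks bad voxels", {
  dims <- c(3, 3, 3)
  s0 <- array(1000, dims)

  # no decay: identical signals give sADC 0 everywhere
  m0 <- compute_sadc_map(dwi_series(s0, s0))
  expect_true(all(m0$values == 0))
  expect_true(all(m0$valid_mask))

  # closed-form round trip: S1500 = 1000/exp(1300 * 0.69e-3) recovers 0.69
  s_hi <- array(1000 / exp(1300 * 0.69e-3), dims)
  m <- compute_sadc_map(dwi_series(s0, s_hi))
  expect_equal(m$values[1, 1, 1], 0.69, tolerance = 1e-12)

  # zero signal at a voxel invalidates that voxel only
  s_hi[2, 2, 2] <- 0
  m2 <- compute_sadc_map(dwi_series(s0, s_hi))
  expect_false(m2$valid_mask[2, 2, 2])
  expect_true(is.na(m2$values[2, 2, 2]))
  expect_equal(sum(!m2$valid_mask), 1L)

  # negative sADC retained in values but excluded from the physical mask
  s_neg <- array(1000, dims); s_neg_hi <- array(1200, dims)
  mneg <- compute_sadc_map(dwi_series(s_neg, s_neg_hi))
  expect_true(all(mneg$values < 0))
  expect_true(all(mneg$valid_mask))
  expect_false(any(mneg$physical_mask))
})

test_that("sADC matches an independent scalar-loop oracle on random volumes", {
  set.seed(101)
  for (i in 1:5) {
    dims <- c(4, 5, 3)
    s_lo <- array(runif(prod(dims), 0, 2000), dims)
    s_hi <- array(runif(prod(dims), 0, 2000), dims)
    s_lo[sample(prod(dims), 3)] <- 0   # some invalid voxels
    m <- compute_sadc_map(dwi_series(s_lo, s_hi))
    expect_equal(m$values, oracle_sadc_loop(s_lo, s_hi), tolerance = 1e-12)
  }
})

test_that("stiffness conversion is the published affine map and inverts exactly", {
  cal <- calibration_params()
  dims <- c(2, 2, 2)
  sadc <- vmre:::new_parametric_map(array(0.69, dims), "sadc_e3_mm2_per_s",
                                    array(TRUE, dims), diag(4), c(1, 1, 1))
  vm <- sadc_to_vmre(sadc, cal)
  expect_equal(round(vm$values[1], 2), 5.21)   # printed F1 anchor
  expect_identical(vm$unit, "kPa")

  # intercept and root of the line
  z <- sadc; z$values[] <- 0
  expect_equal(sadc_to_vmre(z, cal)$values[1], 14.0)
  r <- sadc; r$values[] <- 14.0 / 12.740
  expect_equal(sadc_to_vmre(r, cal)$values[1], 0, tolerance = 1e-12)

  # round trip kPa -> sADC -> kPa
  back <- sadc_to_vmre(vmre_to_sadc(vm, cal), cal)
  expect_equal(back$values, vm$values, tolerance = 1e-9)

  # unit discipline
  expect_error(sadc_to_vmre(vm, cal), "unit")
  expect_error(vmre_to_sadc(sadc, cal), "unit")
  # degenerate calibration is rejected at construction
  expect_error(calibration_params(alpha = 0), "alpha")
})

test_that("the affine conversion commutes with masked voxelwise averaging", {
  set.seed(7)
  cal <- calibration_params()
  dims <- c(6, 6, 4)
  vals <- array(runif(prod(dims), 0.3, 1.2), dims)
  mask <- array(runif(prod(dims)) > 0.4, dims)
  sadc <- vmre:::new_parametric_map(vals, "sadc_e3_mm2_per_s",
                                    array(TRUE, dims), diag(4), c(1, 1, 1))
  vm <- sadc_to_vmre(sadc, cal)
  expect_equal(mean(vm$values[mask]),
               cal$alpha * mean(vals[mask]) + cal$beta, tolerance = 1e-12)
  # monotonicity: alpha < 0 makes VMRE strictly decreasing in sADC
  o <- order(vals)
  expect_true(all(diff(vm$values[o]) <= 0))
})

test_that("color-map export clamps to the window and renders invalid voxels as background", {
  dims <- c(4, 4, 2)
  tmp <- withr::local_tempdir()
  lo_map <- make_constant_map(2, dims)
  hi_map <- make_constant_map(9, dims)
  over <- make_constant_map(99, dims)
  p1 <- export_color_map(lo_map, c(2, 9), out_prefix = file.path(tmp, "lo"),
                         slices = 1)
  p2 <- export_color_map(hi_map, c(2, 9), out_prefix = file.path(tmp, "hi"),
                         slices = 1)
  p3 <- export_color_map(over, c(2, 9), out_prefix = file.path(tmp, "ov"),
                         slices = 1)
  img1 <- png::readPNG(p1); img2 <- png::readPNG(p2); img3 <- png::readPNG(p3)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "Inferno")) / 255
  expect_equal(as.numeric(img1[1, 1, ]), as.numeric(pal[, 1]), tolerance = 1/255)
  expect_equal(as.numeric(img2[1, 1, ]), as.numeric(pal[, 256]), tolerance = 1/255)
  expect_equal(img3, img2)  # out-of-window clamps to the nearer end
  # uniform plane
  expect_true(all(apply(img1, 3, function(ch) length(unique(c(ch))) == 1)))

  inv <- lo_map; inv$valid_mask[] <- FALSE
  expect_warning(p4 <- export_color_map(inv, c(2, 9),
                                        out_prefix = file.path(tmp, "bg"),
                                        slices = 1), "empty valid mask")
  img4 <- png::readPNG(p4)
  expect_true(all(img4 == 0))
})

test_that("NIfTI round trip preserves signals and geometry", {
  tmp <- withr::local_tempdir()
  dims <- c(5, 4, 3)
  s_lo <- array(runif(prod(dims), 100, 1000), dims)
  s_hi <- array(runif(prod(dims), 100, 1000), dims)
  write_volume_nifti(s_lo, file.path(tmp, "b200.nii.gz"), c(4, 4, 6))
  write_volume_nifti(s_hi, file.path(tmp, "b1500.nii.gz"), c(4, 4, 6))
  dwi <- read_dwi_nifti(file.path(tmp, "b200.nii.gz"),
                        file.path(tmp, "b1500.nii.gz"))
  expect_equal(dwi$signal_low_b, s_lo, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(dwi$voxel_size_mm, c(4, 4, 6))
  m <- compute_sadc_map(dwi)
  expect_equal(m$values, oracle_sadc_loop(s_lo, s_hi), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("mismatched geometry is rejected", {
  expect_error(dwi_series(array(1, c(2, 2, 2)), array(1, c(2, 2, 3))), "shape")
  expect_error(dwi_series(array(1, c(2, 2, 2)), array(1, c(2, 2, 2)),
                          b_low = 1500, b_high = 200), "b_high")
})
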