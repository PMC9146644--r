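test_that("NIfTI round trip preserves data, spacing and origin", {
  set.seed(7)
  v <- as_volume(array(rnorm(16 * 12 * 6), c(16, 12, 6)),
                 spacing = c(0.3125, 0.3125, 3.0), origin = c(-5, 2.5, 10))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  r <- read_volume(path)
  expect_equal(r$data, v$data, tolerance = 1e-6)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-6)
  # header fields propagate verbatim (independent header dump as oracle)
  hdr <- RNifti::niftiHeader(RNifti::readNifti(path))
  expect_equal(as.numeric(hdr$pixdim[2:4]), c(0.3125, 0.3125, 3.0),
               tolerance = 1e-6)
  # masks round trip as uint8
  m <- as_mask(array(as.integer(v$data > 0), dim(v$data)), v$spacing, v$origin)
  mpath <- tempfile(fileext = ".nii.gz")
  write_volume(m, mpath)
  rm_ <- read_volume(mpath, mask = TRUE)
  expect_identical(rm_$data, m$data)
})

test_that("reader rejects bad inputs with clear errors", {
  expect_error(read_volume(tempfile()), "not found")
  txt <- tempfile(fileext = ".nii")
  writeLines("this is not a nifti", txt)
  expect_error(read_volume(txt), "NIfTI")
  # 4D payload
  arr4 <- array(0, c(4, 4, 2, 3))
  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr4), p4)
  expect_error(read_volume(p4), "3D")
})

test_that("volume/mask constructors enforce their invariants", {
  expect_error(as_volume(matrix(0, 2, 2)), "3D")
  expect_error(as_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(as_volume(array(c(1, NA), c(2, 1, 1))), "finite")
  expect_error(as_mask(array(2, c(2, 2, 2))), "0 or 1")
})

test_that("isotropic resampling preserves extent, values and mask volume", {
  const <- as_volume(array(5, c(10, 10, 4)), spacing = c(1, 1, 3))
  r <- resample_isotropic(const, 0.5)
  expect_equal(r$spacing, rep(0.5, 3))
  expect_true(all(abs(r$data - 5) < 1e-6))
  # physical extent preserved within one voxel
  expect_true(all(abs(dim(r$data) * 0.5 - dim(const$data) * const$spacing)
                  <= 0.5 + 1e-9))

  ball <- ball_mask(r_mm = 10, spacing = c(1, 1, 3))
  iso <- resample_isotropic(ball, 0.5)
  expect_true(all(iso$data %in% c(0L, 1L)))
  v_analytic <- 4 / 3 * pi * 10^3
  expect_lt(abs(mask_volume_mm3(iso) - v_analytic) / v_analytic, 0.05)

  expect_error(resample_isotropic(ball, 0), "positive")
  expect_error(resample_isotropic(ball, 0.5, mode = "cubic"), "nearest")
})

test_that("resampling to a reference grid restores the native grid", {
  ball <- ball_mask(r_mm = 10, spacing = c(1, 1, 3))
  iso <- resample_isotropic(ball, 0.5)
  back <- resample_to_grid(iso, ball)
  expect_identical(dim(back$data), dim(ball$data))
  expect_equal(back$spacing, ball$spacing)
  expect_gte(dsc(back, ball), 0.95)
  # reference == vol is the identity
  same <- resample_to_grid(ball, ball)
  expect_identical(same$data, ball$data)
  # disjoint extents warn and return zeros
  far <- as_volume(array(1, c(4, 4, 4)), origin = c(1000, 1000, 1000))
  expect_warning(z <- resample_to_grid(far, ball_mask(5)), "disjoint")
  expect_true(all(z$data == 0))
})
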