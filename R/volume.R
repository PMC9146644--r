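#' 3D image volumes and binary masks
#'
#' A `prostasm_volume` carries a 3D scalar array together with its physical
#' geometry: voxel spacing `(sx, sy, sz)` in mm and the physical position of
#' the first voxel centre (`origin`, mm). The physical position of 0-based
#' voxel index `(i, j, k)` is `origin + index * spacing`; every mesh and
#' vertex coordinate in the package lives in this frame. A `prostasm_mask` is
#' a volume whose values are restricted to `{0, 1}`.
#'
#' @param data numeric 3D array; all values must be finite.
#' @param spacing numeric length-3, voxel spacing in mm, strictly positive.
#' @param origin numeric length-3, physical position (mm) of voxel (0,0,0).
#' @return `as_volume()` returns a `prostasm_volume`; `as_mask()` returns a
#'   `prostasm_mask` (which is also a `prostasm_volume`).
#' @examples
#' v <- as_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 3))
#' m <- as_mask(array(0L, c(8, 8, 4)), spacing = c(1, 1, 3))
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ",
         paste(dim(data), collapse = "x"), call. = FALSE)
  if (length(data) == 0L) stop("volume array is empty", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers (mm)", call. = FALSE)
  if (any(!is.finite(data))) stop("volume contains non-finite values",
                                  call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "prostasm_volume")
}

#' @rdname as_volume
#' @export
as_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  }
  v <- as_volume(data, spacing, origin)
  if (!all(v$data %in% c(0, 1)))
    stop("mask values must be 0 or 1", call. = FALSE)
  storage.mode(v$data) <- "integer"
  class(v) <- c("prostasm_mask", class(v))
  v
}

#' @rdname as_volume
#' @param x object to test.
#' @export
is_volume <- function(x) inherits(x, "prostasm_volume")

#' @rdname as_volume
#' @export
is_mask <- function(x) inherits(x, "prostasm_mask")

#' @export
print.prostasm_volume <- function(x, ...) {
  kind <- if (is_mask(x)) "binary mask" else "volume"
  cat(sprintf("<prostasm %s> %s voxels, spacing %s mm, origin %s mm\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  if (is_mask(x)) {
    cat(sprintf("  foreground voxels: %d (%.1f mL)\n", sum(x$data),
                mask_volume_mm3(x) / 1000))
  } else {
    cat(sprintf("  intensity range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

# same-grid check used throughout
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " are not on the same grid (shape/spacing/origin differ)",
         call. = FALSE)
  invisible(TRUE)
}

#' Foreground volume of a mask in cubic millimetres
#' @param mask a `prostasm_mask`.
#' @return scalar, mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(is_mask(mask))
  sum(mask$data) * prod(mask$spacing)
}

# physical coordinates (mm) of foreground voxel centres, n x 3
mask_points_mm <- function(mask) {
  idx <- which(mask$data == 1L, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file (`.nii` / `.nii.gz`) into a [as_volume()] object.
#' Only axis-aligned geometries are supported: a file whose affine contains
#' an oblique rotation or axis flip is rejected with an error. 2D or 4D
#' payloads are rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask logical; read as a binary mask (values validated to `{0,1}`).
#' @return a `prostasm_volume` (or `prostasm_mask` when `mask = TRUE`).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D payload in ", path,
         call. = FALSE)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  sp <- sqrt(colSums(rot^2))
  offdiag <- rot
  diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(sp)) || any(diag(rot) < 0))
    stop("oblique or flipped NIfTI orientation is not supported: ", path,
         call. = FALSE)
  vol <- array(as.numeric(img), dim = d)
  origin <- as.numeric(xf[1:3, 4])
  if (mask) as_mask(vol, sp, origin) else as_volume(vol, sp, origin)
}

#' Write a volume or mask to NIfTI-1
#'
#' Masks are stored as unsigned 8-bit integers, volumes as 32-bit floats.
#' The affine encodes spacing and origin only (axis-aligned RAS).
#'
#' @param vol a `prostasm_volume` or `prostasm_mask`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  dtype <- if (is_mask(vol)) "uint8" else "float"
  img <- RNifti::asNifti(structure(vol$data, pixdim = vol$spacing),
                         datatype = dtype)
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

.mode_code <- function(mode) {
  switch(mode, nearest = 0L, linear = 1L, cubic = 2L,
         stop("unknown interpolation mode: ", mode, call. = FALSE))
}

#' Resample a volume to an isotropic grid
#'
#' Resamples to cubic voxels of edge `target` mm, preserving the physical
#' extent to within one voxel. Intensity volumes use cubic interpolation by
#' default; binary masks must use (and default to) nearest neighbour, which
#' preserves the `{0,1}` value set. Samples beyond the input extent take the
#' edge value.
#'
#' @param vol a `prostasm_volume` or `prostasm_mask`.
#' @param target isotropic voxel size in mm, strictly positive (default 0.5).
#' @param mode `"cubic"`, `"linear"` or `"nearest"`; masks require
#'   `"nearest"`.
#' @return resampled volume of the same class.
#' @export
resample_isotropic <- function(vol, target = 0.5,
                               mode = if (is_mask(vol)) "nearest" else "cubic") {
  stopifnot(is_volume(vol))
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target) ||
      target <= 0)
    stop("target voxel size must be a positive number (mm)", call. = FALSE)
  if (is_mask(vol) && mode != "nearest")
    stop("binary masks must be resampled with mode = \"nearest\"",
         call. = FALSE)
  d <- dim(vol$data)
  extent <- d * vol$spacing
  odim <- pmax(1L, as.integer(round(extent / target)))
  oorigin <- vol$origin + (target - vol$spacing) / 2
  out <- cpp_resample_grid(as.numeric(vol$data), d, vol$spacing, vol$origin,
                           odim, rep(target, 3), oorigin, .mode_code(mode))
  arr <- array(out, odim)
  if (is_mask(vol)) as_mask(arr, rep(target, 3), oorigin)
  else as_volume(arr, rep(target, 3), oorigin)
}

#' Resample a volume onto the grid of a reference volume
#'
#' @param vol volume to resample.
#' @param reference volume whose grid (shape, spacing, origin) defines the
#'   output.
#' @param mode interpolation mode; masks require `"nearest"`.
#' @return volume of `vol`'s class on `reference`'s grid. If the physical
#'   extents of `vol` and `reference` do not overlap, a warning is issued and
#'   a zero-filled volume is returned.
#' @export
resample_to_grid <- function(vol, reference,
                             mode = if (is_mask(vol)) "nearest" else "cubic") {
  stopifnot(is_volume(vol), is_volume(reference))
  if (is_mask(vol) && mode != "nearest")
    stop("binary masks must be resampled with mode = \"nearest\"",
         call. = FALSE)
  rd <- dim(reference$data)
  lo_v <- vol$origin - vol$spacing / 2
  hi_v <- vol$origin + (dim(vol$data) - 0.5) * vol$spacing
  lo_r <- reference$origin - reference$spacing / 2
  hi_r <- reference$origin + (rd - 0.5) * reference$spacing
  if (any(hi_v < lo_r) || any(lo_v > hi_r)) {
    warning("physical extents of volume and reference are disjoint; ",
            "returning a zero-filled volume")
    arr <- array(if (is_mask(vol)) 0L else 0, rd)
  } else {
    out <- cpp_resample_grid(as.numeric(vol$data), dim(vol$data), vol$spacing,
                             vol$origin, rd, reference$spacing,
                             reference$origin, .mode_code(mode))
    arr <- array(out, rd)
  }
  if (is_mask(vol)) as_mask(arr, reference$spacing, reference$origin)
  else as_volume(arr, reference$spacing, reference$origin)
}

#' Sample a volume at arbitrary physical points
#'
#' @param vol a `prostasm_volume`.
#' @param points n x 3 matrix of physical mm coordinates.
#' @param mode `"cubic"` (default), `"linear"` or `"nearest"`. Out-of-extent
#'   points take the edge value.
#' @return numeric vector of length n.
#' @export
sample_volume <- function(vol, points, mode = "cubic") {
  stopifnot(is_volume(vol))
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_sample_points(as.numeric(vol$data), dim(vol$data), vol$spacing,
                    vol$origin, points, .mode_code(mode))
}
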