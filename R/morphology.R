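# Binary-morphology helpers shared by the phantom, post-processing and
# metrics modules. All distances are Euclidean in mm, computed with an exact
# separable distance transform that honours anisotropic voxel spacing.

# squared distance (mm^2) from every voxel to the nearest foreground voxel
edt_sq <- function(mask) {
  stopifnot(is_mask(mask))
  array(cpp_edt_sq(mask$data == 1L, dim(mask$data), mask$spacing),
        dim(mask$data))
}

# signed distance: positive inside the mask, negative outside (mm)
signed_distance <- function(mask) {
  inside <- sqrt(edt_sq(invert_mask(mask)))
  outside <- sqrt(edt_sq(mask))
  d <- inside - outside
  d[!is.finite(d)] <- 0
  d
}

invert_mask <- function(mask) {
  as_mask(1L - mask$data, mask$spacing, mask$origin)
}

#' Morphological operations on binary masks
#'
#' Dilation, erosion and closing with a Euclidean ball of radius `r_mm`
#' (exact distance-transform formulation, anisotropic spacing honoured), hole
#' filling, and connected-component utilities.
#'
#' @param mask a `prostasm_mask`.
#' @param r_mm ball radius in mm; `0` is the identity.
#' @return a `prostasm_mask` on the same grid.
#' @name morphology
NULL

#' @rdname morphology
#' @export
dilate_mask <- function(mask, r_mm) {
  stopifnot(is_mask(mask), r_mm >= 0)
  if (r_mm == 0 || sum(mask$data) == 0) return(mask)
  d <- edt_sq(mask)
  as_mask(array(as.integer(d <= r_mm^2 + 1e-9), dim(mask$data)),
          mask$spacing, mask$origin)
}

#' @rdname morphology
#' @export
erode_mask <- function(mask, r_mm) {
  stopifnot(is_mask(mask), r_mm >= 0)
  if (r_mm == 0) return(mask)
  invert_mask(dilate_mask(invert_mask(mask), r_mm))
}

#' @rdname morphology
#' @export
close_mask <- function(mask, r_mm) {
  erode_mask(dilate_mask(mask, r_mm), r_mm)
}

#' @rdname morphology
#' @param per_slice fill 2D holes slice-by-slice (axial) instead of 3D
#'   cavities.
#' @export
fill_holes <- function(mask, per_slice = FALSE) {
  stopifnot(is_mask(mask))
  f <- if (per_slice) cpp_fill_holes2d else cpp_fill_holes3d
  as_mask(array(as.integer(f(mask$data == 1L, dim(mask$data))),
                dim(mask$data)), mask$spacing, mask$origin)
}

#' @rdname morphology
#' @param connectivity 6 or 26.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is_mask(mask), connectivity %in% c(6, 26))
  array(cpp_label_components(mask$data == 1L, dim(mask$data),
                             as.integer(connectivity)), dim(mask$data))
}

#' @rdname morphology
#' @export
keep_largest_component <- function(mask, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  if (max(lab) <= 1L) return(mask)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  as_mask(array(as.integer(lab == keep), dim(mask$data)), mask$spacing,
          mask$origin)
}

#' @rdname morphology
#' @export
n_components <- function(mask, connectivity = 26) {
  max(label_components(mask, connectivity))
}

# foreground voxels with at least one of their 6 neighbours outside the mask
# (array borders count as background)
surface_voxel_indices <- function(mask) {
  a <- mask$data == 1L
  d <- dim(a)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  core <- function(dx, dy, dz)
    p[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy, (2:(d[3] + 1)) + dz,
      drop = FALSE]
  interior <- core(1, 0, 0) & core(-1, 0, 0) & core(0, 1, 0) &
    core(0, -1, 0) & core(0, 0, 1) & core(0, 0, -1)
  which(a & !interior, arr.ind = TRUE)
}

#' Physical coordinates of a mask's surface voxels
#'
#' Surface voxels are foreground voxels with at least one 6-neighbour in the
#' background (the array border counts as background).
#'
#' @param mask a `prostasm_mask`.
#' @return n x 3 matrix of mm coordinates.
#' @export
surface_points_mm <- function(mask) {
  idx <- surface_voxel_indices(mask)
  sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

# global-histogram Otsu threshold of a numeric array (256 bins)
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0)
    stop("degenerate histogram: constant-intensity volume", call. = FALSE)
  h <- tabulate(pmin(256L, 1L + as.integer(255 * (x - rng[1]) / diff(rng))),
                nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + (k / 256) * diff(rng)
}
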