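#' Triangulate refined vertices into a closed surface mesh
#'
#' Alpha-shape triangulation of a corresponded vertex set (default
#' `alpha = 30` mm, coarser than the correspondence stage because the vertex
#' cloud is sparse). Errors if the result is not a single closed surface.
#'
#' For sparse vertex clouds the alpha complex can fall apart at the
#' nominal radius (tetrahedra near flat regions have circumradii close to
#' the local curvature radius); if the surface is not a single closed
#' component the radius is doubled, up to the convex-hull limit, and the
#' first closed surface is returned.
#'
#' @param shape a `prostasm_shape` (or K x 3 matrix), K >= 4, not coplanar.
#' @param alpha alpha radius in mm.
#' @return a `prostasm_mesh`.
#' @export
mesh_from_vertices <- function(shape, alpha = 30) {
  pts <- shape_matrix(as_shape(shape))
  a <- alpha
  for (try in 1:12) {
    mesh <- tryCatch(alpha_triangulate(pts, a, require_closed = TRUE),
                     error = function(e) NULL)
    if (!is.null(mesh)) return(mesh)
    a <- a * 2
  }
  # surface last attempt's error
  alpha_triangulate(pts, a, require_closed = TRUE)
}

#' Slice a mesh into per-plane boundary polygons
#'
#' For every axial (z) plane of the grid that crosses the mesh, casts
#' in-plane rays from the mesh centroid's (x, y) position at a fixed angular
#' step and keeps, per ray, the farthest ray-triangle intersection — the
#' outermost surface point. Planes with fewer than 3 hits are marked empty.
#'
#' @param mesh a `prostasm_mesh`.
#' @param grid list with `dim`, `spacing`, `origin` (or a
#'   `prostasm_volume`).
#' @param angular_step in-plane ray step in degrees (default 11.25, i.e. 32
#'   rays).
#' @return list of per-slice polygons: `list(z_index, points)` with `points`
#'   an n x 2 matrix of (x, y) mm, ordered by angle, or `NULL` points for
#'   empty slices.
#' @export
slice_contours <- function(mesh, grid, angular_step = 11.25) {
  if (is_volume(grid))
    grid <- list(dim = dim(grid$data), spacing = grid$spacing,
                 origin = grid$origin)
  ctr <- colMeans(mesh$vertices)
  zs <- grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$spacing[3]
  ang <- seq(0, 360 - angular_step, by = angular_step) * pi / 180
  n_ray <- length(ang)
  out <- vector("list", grid$dim[3])
  zmin <- min(mesh$vertices[, 3])
  zmax <- max(mesh$vertices[, 3])
  for (k in seq_len(grid$dim[3])) {
    if (zs[k] < zmin - 1e-9 || zs[k] > zmax + 1e-9) {
      out[[k]] <- list(z_index = k, points = NULL)
      next
    }
    origins <- cbind(ctr[1], ctr[2], zs[k])[rep(1, n_ray), , drop = FALSE]
    dirs <- cbind(cos(ang), sin(ang), 0)
    hits <- ray_mesh_farthest(origins, dirs, mesh)
    ok <- which(!is.na(hits$t))
    if (length(ok) < 3) {
      out[[k]] <- list(z_index = k, points = NULL)
      next
    }
    pts <- cbind(ctr[1] + hits$t[ok] * cos(ang[ok]),
                 ctr[2] + hits$t[ok] * sin(ang[ok]))
    out[[k]] <- list(z_index = k, points = pts)
  }
  out
}

#' Rasterise slice polygons into the final binary mask
#'
#' Fills each slice polygon (even-odd rule on the angularly ordered
#' boundary), stacks the slices, fills 2D then 3D holes, applies a 3D
#' morphological closing with a spherical element, and resamples the result
#' onto the reference grid with nearest-neighbour interpolation.
#'
#' @param polygons output of [slice_contours()].
#' @param grid the isotropic working grid (`dim`, `spacing`, `origin` list
#'   or a volume).
#' @param reference `prostasm_volume`/`prostasm_mask` defining the output
#'   grid (e.g. the native-resolution input volume).
#' @param closing_radius_vox radius of the spherical closing element in
#'   (isotropic) voxels (default 4); 0 skips the closing.
#' @return a `prostasm_mask` on the reference grid.
#' @export
finalize_mask <- function(polygons, grid, reference, closing_radius_vox = 4) {
  if (is_volume(grid))
    grid <- list(dim = dim(grid$data), spacing = grid$spacing,
                 origin = grid$origin)
  nonempty <- Filter(function(p) !is.null(p$points), polygons)
  if (length(nonempty) == 0)
    stop("all slices are empty; nothing to rasterise", call. = FALSE)
  arr <- array(FALSE, grid$dim)
  for (p in polygons) {
    if (is.null(p$points)) next
    sl <- cpp_fill_polygon(grid$dim[1], grid$dim[2], p$points[, 1],
                           p$points[, 2], grid$origin[1], grid$origin[2],
                           grid$spacing[1], grid$spacing[2])
    arr[, , p$z_index] <- matrix(sl, grid$dim[1], grid$dim[2])
  }
  # morphology on the bounding box (plus a closing-radius margin) only
  idx <- which(arr, arr.ind = TRUE)
  pad <- closing_radius_vox + 2L
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, grid$dim)
  sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ms <- as_mask(array(as.integer(sub), dim(sub)), grid$spacing,
                grid$origin + (lo - 1) * grid$spacing)
  ms <- fill_holes(ms, per_slice = TRUE)
  ms <- fill_holes(ms, per_slice = FALSE)
  if (closing_radius_vox > 0)
    ms <- close_mask(ms, closing_radius_vox * grid$spacing[1])
  arr[] <- FALSE
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- ms$data == 1L
  m <- as_mask(array(as.integer(arr), grid$dim), grid$spacing, grid$origin)
  out <- resample_to_grid(m, reference, mode = "nearest")
  as_mask(out$data, out$spacing, out$origin)
}

#' Convert a refined shape directly to a mask on a reference grid
#'
#' Convenience wrapper chaining [mesh_from_vertices()], [slice_contours()]
#' on the isotropic working grid and [finalize_mask()].
#'
#' @param shape refined `prostasm_shape`.
#' @param iso_grid isotropic working grid (volume or `dim`/`spacing`/
#'   `origin` list).
#' @param reference output grid volume.
#' @param alpha triangulation alpha (mm, default 30).
#' @param angular_step slicing ray step in degrees.
#' @param closing_radius_vox closing radius in isotropic voxels.
#' @return a `prostasm_mask` on `reference`'s grid.
#' @export
shape_to_mask <- function(shape, iso_grid, reference, alpha = 30,
                          angular_step = 11.25, closing_radius_vox = 4) {
  mesh <- mesh_from_vertices(shape, alpha = alpha)
  polys <- slice_contours(mesh, iso_grid, angular_step = angular_step)
  finalize_mask(polys, iso_grid, reference,
                closing_radius_vox = closing_radius_vox)
}
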