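#' Fit an axis-aligned ellipsoid to a mask's surface
#'
#' Algebraic least-squares fit of `A x^2 + B y^2 + C z^2 + D x + E y + F z
#' = 1` to the mask's surface voxels, constrained to an ellipsoid
#' (`A, B, C > 0`). From the fitted centre and sorted radii two pairs of key
#' reference points are derived: `F_xy = centre +/- (c_xy / 2) * e_y` with
#' `c_xy = sqrt(radius_max^2 - radius_min^2)` (the planar focal distance)
#' and `F_xz = centre +/- (c_xz / 2) * e_x` with `c_xz = radius_min`. These
#' key points, together with the centre, later serve as ray sources for
#' correspondence extraction.
#'
#' Two estimators are available. `"moments"` (default) places the centre at
#' the foreground centre of mass and derives the semi-axes from the second
#' moments of the solid (`r_i = sqrt(5 * var_i)`, exact for a solid
#' ellipsoid, with a `spacing^2 / 12` voxel-extent correction): because it
#' integrates over the whole gland it is insensitive to voxelisation of the
#' boundary, which matters because the key points feed the ray sources of
#' the correspondence stage. `"surface-ls"` is the algebraic least-squares
#' quadric through the surface voxels, constrained to an axis-aligned
#' ellipsoid.
#'
#' @param mask a `prostasm_mask` with at least 10 surface voxels.
#' @param method `"moments"` (default) or `"surface-ls"`.
#' @return a `prostasm_ellipsoid`: `centre`, `radii` (sorted decreasing),
#'   `axis_radii` (per x/y/z axis), `c_xy`, `c_xz` and `key_points`
#'   (4 x 3 matrix: F_xy+, F_xy-, F_xz+, F_xz-).
#' @export
fit_ellipsoid <- function(mask, method = c("moments", "surface-ls")) {
  method <- match.arg(method)
  stopifnot(is_mask(mask))
  pts <- surface_points_mm(mask)
  if (nrow(pts) < 10)
    stop("too few surface voxels (", nrow(pts), ") for an ellipsoid fit",
         call. = FALSE)
  sv <- svd(sweep(pts, 2, colMeans(pts), `-`), nu = 0, nv = 0)$d
  if (sv[3] < 1e-6 * max(sv[1], 1))
    stop("surface points are degenerate (coplanar); cannot fit an ellipsoid",
         call. = FALSE)
  if (method == "moments") {
    fg <- mask_points_mm(mask)
    centre <- colMeans(fg)
    v <- apply(fg, 2, var) + mask$spacing^2 / 12
    if (any(v <= 0)) stop("degenerate ellipsoid fit", call. = FALSE)
    axis_radii <- sqrt(5 * v)
  } else {
    # fit in centroid-centred coordinates so the quadric normalisation
    # (right-hand side 1) keeps a positive-definite quadratic part
    mu <- colMeans(pts)
    pc <- sweep(pts, 2, mu)
    X <- cbind(pc[, 1]^2, pc[, 2]^2, pc[, 3]^2, pc)
    beta <- tryCatch(qr.solve(X, rep(1, nrow(pts))), error = function(e)
      stop("ellipsoid fit failed: ", conditionMessage(e), call. = FALSE))
    if (any(beta[1:3] <= 0))
      stop("least-squares quadric is not an ellipsoid", call. = FALSE)
    centre0 <- -beta[4:6] / (2 * beta[1:3])
    g <- 1 + sum(beta[1:3] * centre0^2)
    if (g <= 0) stop("degenerate ellipsoid fit", call. = FALSE)
    axis_radii <- sqrt(g / beta[1:3])
    centre <- centre0 + mu
  }
  radii <- sort(axis_radii, decreasing = TRUE)
  c_xy <- sqrt(max(radii[1]^2 - radii[3]^2, 0))
  c_xz <- radii[3]
  key <- rbind(centre + c(0, c_xy / 2, 0),
               centre - c(0, c_xy / 2, 0),
               centre + c(c_xz / 2, 0, 0),
               centre - c(c_xz / 2, 0, 0))
  rownames(key) <- c("F_xy+", "F_xy-", "F_xz+", "F_xz-")
  structure(list(centre = centre, radii = radii, axis_radii = axis_radii,
                 c_xy = c_xy, c_xz = c_xz, key_points = key),
            class = "prostasm_ellipsoid")
}

#' Ray-casting configuration for correspondence extraction
#'
#' Defines the fixed ray fan shared by every shape entering one model:
#' sources are the ellipsoid centre plus the four key points; directions are
#' `n_azimuth` equally spaced azimuths (step 360 / n_azimuth degrees)
#' crossed with an elevation fan. The vertex count is
#' `K = (1 + 4) * n_azimuth * length(elevations)`.
#'
#' @param alpha alpha radius (mm) for the surface triangulation (default 50).
#' @param n_azimuth number of azimuthal directions (default 8).
#' @param elevations elevation angles in degrees (default 7 values from
#'   -67.5 to 67.5).
#' @param max_surface_points surface voxels are deterministically thinned to
#'   at most this many before triangulation (default 1500).
#' @return a `prostasm_ray_config`.
#' @export
ray_config <- function(alpha = 50, n_azimuth = 8,
                       elevations = seq(-67.5, 67.5, length.out = 7),
                       max_surface_points = 1500) {
  structure(list(alpha = alpha, n_azimuth = as.integer(n_azimuth),
                 elevations = elevations,
                 max_surface_points = as.integer(max_surface_points)),
            class = "prostasm_ray_config")
}

ray_config_K <- function(cfg) {
  5L * cfg$n_azimuth * length(cfg$elevations)
}

# unit directions of the fan, ordered elevation-major then azimuth
ray_directions <- function(cfg) {
  az <- (seq_len(cfg$n_azimuth) - 1) * 2 * pi / cfg$n_azimuth
  el <- cfg$elevations * pi / 180
  g <- expand.grid(az = az, el = el)  # azimuth varies fastest
  cbind(cos(g$el) * cos(g$az), cos(g$el) * sin(g$az), sin(g$el))
}

#' Extract corresponded surface vertices from a mask
#'
#' Produces the fixed-length, consistently ordered vertex list that makes
#' shapes comparable across subjects: the mask's surface voxels are
#' triangulated with the alpha shape, rays are cast from the five ellipsoid
#' key sources along the configured direction fan, and for every ray the
#' farthest ray-mesh intersection is recorded. The ordering is
#' (source, elevation, azimuth)-lexicographic and identical for every mask,
#' so vertex k corresponds across shapes.
#'
#' A detached foreground blob that intercepts a ray beyond the gland will
#' capture that ray's vertex; callers refining noisy network output should
#' clean the mask (largest component, hole fill) first.
#'
#' @param mask a `prostasm_mask` on an isotropic grid (resample first).
#' @param config a [ray_config()].
#' @return a `prostasm_shape`: K x 3 matrix of mm vertices with the config
#'   as attribute.
#' @export
extract_corresponded_vertices <- function(mask, config = ray_config()) {
  stopifnot(is_mask(mask), inherits(config, "prostasm_ray_config"))
  if (max(mask$spacing) - min(mask$spacing) > 1e-6)
    stop("mask must be on an isotropic grid; use resample_isotropic()",
         call. = FALSE)
  fit <- fit_ellipsoid(mask)
  pts <- surface_points_mm(mask)
  if (nrow(pts) > config$max_surface_points) {
    keep <- round(seq(1, nrow(pts), length.out = config$max_surface_points))
    pts <- pts[keep, , drop = FALSE]
  }
  mesh <- alpha_triangulate(pts, config$alpha, require_closed = FALSE)
  dirs <- ray_directions(config)
  sources <- rbind(centre = fit$centre, fit$key_points)
  n_dir <- nrow(dirs)
  origins <- sources[rep(seq_len(5), each = n_dir), , drop = FALSE]
  D <- dirs[rep(seq_len(n_dir), times = 5), , drop = FALSE]
  hits <- ray_mesh_farthest(origins, D, mesh)
  if (any(hits$nhits == 0)) {
    bad <- which(hits$nhits == 0)[1]
    src <- (bad - 1) %/% n_dir + 1
    stop(sprintf(paste0("ray %d (source %s, direction %d) does not intersect ",
                        "the surface"), bad, rownames(sources)[src],
                 (bad - 1) %% n_dir + 1), call. = FALSE)
  }
  verts <- origins + hits$t * D
  structure(verts, class = "prostasm_shape", ray_config = config)
}

as_shape <- function(vertices, config = NULL) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3, all(is.finite(vertices)))
  structure(vertices, class = "prostasm_shape", ray_config = config)
}

#' @export
print.prostasm_shape <- function(x, ...) {
  cat(sprintf("<corresponded shape> K = %d vertices, centroid (%s) mm\n",
              nrow(x), paste(round(colMeans(unclass(x)), 1), collapse = ", ")))
  invisible(x)
}

shape_matrix <- function(shape) {
  m <- unclass(shape)
  attr(m, "ray_config") <- NULL
  m
}

# flatten K x 3 -> length 3K (x block, y block, z block)
flatten_shape <- function(shape) as.numeric(shape_matrix(shape))
unflatten_shape <- function(v) matrix(v, ncol = 3)

rot_z <- function(th) matrix(c(cos(th), sin(th), 0,
                               -sin(th), cos(th), 0,
                               0, 0, 1), 3, 3)
rot_y <- function(th) matrix(c(cos(th), 0, -sin(th),
                               0, 1, 0,
                               sin(th), 0, cos(th)), 3, 3)

#' Align a corresponded shape to a reference
#'
#' Removes translation (centroid match) and corrects rotation in two
#' four-quadrant inverse-tangent steps: first about z using the x-y
#' coordinates, then about y using the x-z coordinates. Each angle is the
#' planar Procrustes optimum `atan2(sum(x*y' - y*x'), sum(x*x' + y*y'))`.
#' The returned transform is exactly invertible.
#'
#' @param shape,reference `prostasm_shape`s with the same K.
#' @return `list(shape, transform)`, with `transform` a
#'   `prostasm_alignment` (`theta_z`, `theta_y`, centroids).
#' @export
align_shape <- function(shape, reference) {
  s <- shape_matrix(shape)
  r <- shape_matrix(reference)
  if (nrow(s) != nrow(r))
    stop("shapes have different vertex counts: ", nrow(s), " vs ", nrow(r),
         call. = FALSE)
  cs <- colMeans(s)
  cr <- colMeans(r)
  s0 <- sweep(s, 2, cs)
  r0 <- sweep(r, 2, cr)
  theta_z <- atan2(sum(s0[, 1] * r0[, 2] - s0[, 2] * r0[, 1]),
                   sum(s0[, 1] * r0[, 1] + s0[, 2] * r0[, 2]))
  s1 <- s0 %*% t(rot_z(theta_z))
  theta_y <- atan2(sum(s1[, 3] * r0[, 1] - s1[, 1] * r0[, 3]),
                   sum(s1[, 3] * r0[, 3] + s1[, 1] * r0[, 1]))
  s2 <- s1 %*% t(rot_y(theta_y))
  aligned <- sweep(s2, 2, cr, `+`)
  tf <- structure(list(theta_z = theta_z, theta_y = theta_y,
                       centroid_shape = cs, centroid_reference = cr),
                  class = "prostasm_alignment")
  list(shape = as_shape(aligned, attr(shape, "ray_config")), transform = tf)
}

#' @rdname align_shape
#' @param aligned a shape in the reference frame.
#' @param transform the `prostasm_alignment` returned by `align_shape`.
#' @export
invert_alignment <- function(aligned, transform) {
  a <- shape_matrix(aligned)
  a0 <- sweep(a, 2, transform$centroid_reference)
  s1 <- a0 %*% rot_y(transform$theta_y)
  s0 <- s1 %*% rot_z(transform$theta_z)
  as_shape(sweep(s0, 2, transform$centroid_shape, `+`),
           attr(aligned, "ray_config"))
}

#' Build the point distribution model from aligned shapes
#'
#' PCA of the flattened (3K) shape vectors: the mean shape plus the leading
#' eigenvectors of the shape covariance whose cumulative eigenvalue fraction
#' first reaches `variance` (default 98%). Uses the dual (n x n)
#' decomposition, so cohorts far smaller than 3K are handled exactly.
#'
#' @param shapes list of >= 3 `prostasm_shape`s with equal K, already
#'   aligned to a common frame.
#' @param variance retained total-variance fraction in (0, 1] (default
#'   0.98).
#' @return a `prostasm_shape_model`: `x_mean` (3K), `Ws` (3K x t orthonormal
#'   eigenvectors), `lambda` (t eigenvalues, decreasing), `variance_retained`,
#'   `K`, `n_train`.
#' @export
build_shape_model <- function(shapes, variance = 0.98) {
  if (length(shapes) < 3) stop("need at least 3 shapes for a PCA model",
                               call. = FALSE)
  K <- nrow(shape_matrix(shapes[[1]]))
  X <- t(vapply(shapes, flatten_shape, numeric(3 * K)))
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)
  n <- nrow(X)
  G <- Xc %*% t(Xc) / (n - 1)
  eg <- eigen(G, symmetric = TRUE)
  tot <- sum(pmax(eg$values, 0))
  if (tot <= 1e-12) {
    Ws <- matrix(0, 3 * K, 0)
    lambda <- numeric(0)
    retained <- 1
  } else {
    pos <- which(eg$values > 1e-10 * tot)
    cum <- cumsum(eg$values[pos]) / tot
    t_keep <- which(cum >= variance - 1e-12)[1]
    if (is.na(t_keep)) t_keep <- length(pos)
    sel <- pos[seq_len(t_keep)]
    lambda <- eg$values[sel]
    Ws <- t(Xc) %*% eg$vectors[, sel, drop = FALSE]
    Ws <- sweep(Ws, 2, sqrt((n - 1) * lambda), `/`)
    retained <- cum[t_keep]
  }
  structure(list(x_mean = x_mean, Ws = Ws, lambda = lambda,
                 variance_retained = retained, K = K, n_train = n,
                 target_variance = variance),
            class = "prostasm_shape_model")
}

#' @export
print.prostasm_shape_model <- function(x, ...) {
  cat(sprintf(paste0("<shape model> K = %d vertices, %d mode(s), ",
                     "%.1f%% variance retained (n = %d shapes)\n"),
              x$K, length(x$lambda), 100 * x$variance_retained, x$n_train))
  invisible(x)
}

#' Mean shape of a shape model as a K x 3 shape
#' @param model a `prostasm_shape_model`.
#' @return a `prostasm_shape`.
#' @export
mean_shape <- function(model) {
  as_shape(unflatten_shape(model$x_mean))
}
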