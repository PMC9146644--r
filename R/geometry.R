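#' Alpha-shape surface triangulation of a 3D point cloud
#'
#' Computes the Delaunay tetrahedralisation of the points (incremental
#' insertion with a deterministic sub-voxel jitter that breaks the
#' cospherical degeneracies of grid-aligned clouds), keeps the tetrahedra
#' whose circumradius is at most `alpha` (the alpha complex), and returns the
#' boundary faces, oriented outward. Large `alpha` recovers the convex hull.
#'
#' @param points n x 3 matrix of mm coordinates, n >= 4, not all coplanar.
#' @param alpha alpha radius in mm (> 0).
#' @param require_closed error if the resulting surface is not a single
#'   closed (watertight) component (default TRUE).
#' @return a `prostasm_mesh`: `list(vertices, triangles)` with `triangles`
#'   a T x 3 matrix of 1-based vertex indices.
#' @export
alpha_triangulate <- function(points, alpha, require_closed = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 4)
    stop("need at least 4 points in 3D", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  # coincident points (distinct rays can hit the same surface point) break
  # the incremental triangulation's predicates; collapse them first
  dup <- duplicated(round(points, 5))
  points <- points[!dup, , drop = FALSE]
  if (nrow(points) < 4)
    stop("fewer than 4 distinct points", call. = FALSE)
  # coplanarity check via the singular values of the centred cloud
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr, `-`), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("points are (nearly) coplanar; no 3D surface exists", call. = FALSE)
  res <- cpp_alpha_surface(points, alpha)
  tri <- res$triangles
  if (nrow(tri) == 0)
    stop("alpha = ", alpha, " yields no surface; increase alpha",
         call. = FALSE)
  mesh <- new_mesh(points, tri)
  if (require_closed) {
    chk <- mesh_topology(mesh)
    if (!chk$closed || chk$n_components != 1)
      stop(sprintf(paste0("alpha shape is not a single closed surface ",
                          "(%d component(s), %d unmatched edge(s)); ",
                          "adjust alpha"),
                   chk$n_components, chk$n_open_edges), call. = FALSE)
  }
  mesh
}

new_mesh <- function(vertices, triangles) {
  # drop degenerate (zero-area) triangles
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  cr <- cross3(b - a, c_ - a)
  area2 <- sqrt(rowSums(cr^2))
  keep <- area2 > 1e-12
  structure(list(vertices = vertices,
                 triangles = triangles[keep, , drop = FALSE]),
            class = "prostasm_mesh")
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' @export
print.prostasm_mesh <- function(x, ...) {
  cat(sprintf("<mesh> %d vertices, %d triangles, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

#' Mesh surface area (mm^2)
#' @param mesh a `prostasm_mesh`.
#' @return scalar area.
#' @export
mesh_area <- function(mesh) {
  a <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  sum(sqrt(rowSums(cross3(b - a, c_ - a)^2))) / 2
}

# edge-based closedness / connectivity diagnostics
mesh_topology <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0)
    return(list(closed = FALSE, n_components = 0, n_open_edges = 0))
  ed <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  key <- paste(ed[, 1], ed[, 2])
  cnt <- table(key)
  # connected components over triangles sharing an edge
  used <- sort(unique(as.vector(tr)))
  parent <- seq_along(used)
  idx <- match(as.vector(tr), used)
  dim(idx) <- dim(tr)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(tr))) {
    a <- find(idx[r, 1]); b <- find(idx[r, 2]); c_ <- find(idx[r, 3])
    parent[b] <- a
    parent[c_] <- find(a)
  }
  roots <- vapply(seq_along(used), find, integer(1))
  list(closed = all(cnt == 2), n_components = length(unique(roots)),
       n_open_edges = sum(cnt != 2))
}

#' Ray-triangle intersection (Moller-Trumbore)
#'
#' Intersects the ray `R(t) = O + t D` (`t >= 0`) with a triangle, returning
#' the ray parameter and barycentric coordinates, or `NULL` for a miss.
#' Front and back faces both count as hits.
#'
#' @param origin length-3 ray origin (mm).
#' @param direction length-3 direction; must have non-zero length (it is
#'   normalised internally).
#' @param triangle 3 x 3 matrix, one vertex per row (mm).
#' @param eps determinant tolerance below which the ray is considered
#'   parallel to the triangle plane.
#' @return `list(t, u, v)` with `u >= 0`, `v >= 0`, `u + v <= 1`, or `NULL`.
#' @export
ray_triangle_intersect <- function(origin, direction, triangle,
                                   eps = 1e-12) {
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-300) stop("ray direction must have non-zero length",
                         call. = FALSE)
  d <- direction / nrm
  v0 <- triangle[1, ]
  e1 <- triangle[2, ] - v0
  e2 <- triangle[3, ] - v0
  h <- c(d[2] * e2[3] - d[3] * e2[2],
         d[3] * e2[1] - d[1] * e2[3],
         d[1] * e2[2] - d[2] * e2[1])
  det <- sum(e1 * h)
  if (abs(det) < eps) return(NULL)
  s <- origin - v0
  u <- sum(s * h) / det
  if (u < 0 || u > 1) return(NULL)
  q <- c(s[2] * e1[3] - s[3] * e1[2],
         s[3] * e1[1] - s[1] * e1[3],
         s[1] * e1[2] - s[2] * e1[1])
  v <- sum(d * q) / det
  if (v < 0 || u + v > 1) return(NULL)
  t <- sum(e2 * q) / det
  if (t < 0) return(NULL)
  list(t = t, u = u, v = v)
}

# farthest mesh intersection for a batch of rays; list(t, nhits)
ray_mesh_farthest <- function(origins, directions, mesh) {
  cpp_ray_mesh_farthest(as.matrix(origins), as.matrix(directions),
                        mesh$vertices, mesh$triangles)
}
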