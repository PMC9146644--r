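#' Outward unit normals of a corresponded shape on its mesh
#'
#' For a vertex that appears in the mesh, the normal is the
#' incident-angle-weighted mean of its face normals (angle weighting is
#' insensitive to the irregular triangle shapes alpha meshes produce); a vertex absent from the mesh (e.g.
#' inside a concavity bridged by the alpha shape) takes the normal of the
#' nearest face, provided it lies within `max_dist` mm of that face's
#' centroid neighbourhood. All normals are unit length and oriented outward
#' with respect to the shape centroid.
#'
#' @param shape a `prostasm_shape` (K x 3 mm).
#' @param mesh a `prostasm_mesh` built over (at least) the shape's vertices.
#' @param max_dist association tolerance in mm (default 1).
#' @return K x 3 matrix of unit normals.
#' @export
surface_normals <- function(shape, mesh, max_dist = 1) {
  V <- shape_matrix(shape)
  tr <- mesh$triangles
  a <- mesh$vertices[tr[, 1], , drop = FALSE]
  b <- mesh$vertices[tr[, 2], , drop = FALSE]
  c_ <- mesh$vertices[tr[, 3], , drop = FALSE]
  fn <- cross3(b - a, c_ - a)  # length = 2 * area, orientation = winding
  if (all(sqrt(rowSums(fn^2)) < 1e-12))
    stop("degenerate mesh: all faces have zero area", call. = FALSE)
  centroid <- colMeans(V)
  # map shape vertices onto mesh vertex indices (they normally coincide)
  nn <- RANN::nn2(mesh$vertices, V, k = 1)
  face_ctr <- (a + b + c_) / 3
  fn_unit <- fn / pmax(sqrt(rowSums(fn^2)), 1e-300)
  # interior angle of each face at each of its three corners
  corner_angle <- function(p, q, r) {
    u <- q - p; v <- r - p
    cosang <- rowSums(u * v) /
      pmax(sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)), 1e-300)
    acos(pmin(pmax(cosang, -1), 1))
  }
  ang <- cbind(corner_angle(a, b, c_), corner_angle(b, c_, a),
               corner_angle(c_, a, b))
  normals <- matrix(0, nrow(V), 3)
  for (k in seq_len(nrow(V))) {
    w <- NULL
    if (nn$nn.dists[k, 1] < 1e-6) {
      vi <- nn$nn.idx[k, 1]
      hitcol <- cbind(tr[, 1] == vi, tr[, 2] == vi, tr[, 3] == vi)
      inc <- which(rowSums(hitcol) > 0)
      if (length(inc) > 0)
        w <- ang[cbind(inc, max.col(hitcol[inc, , drop = FALSE]))]
    } else {
      inc <- integer(0)
    }
    if (length(inc) == 0) {
      dd <- sqrt(rowSums(sweep(face_ctr, 2, V[k, ], `-`)^2))
      j <- which.min(dd)
      if (dd[j] > max(max_dist, 1e-6) + max(sqrt(rowSums((b - a)^2))[j],
                                            sqrt(rowSums((c_ - a)^2))[j]))
        stop(sprintf("vertex %d is %.2f mm from the mesh (tolerance %g mm)",
                     k, dd[j], max_dist), call. = FALSE)
      inc <- j
      w <- 1
    }
    nrm <- colSums(fn_unit[inc, , drop = FALSE] * w)
    len <- sqrt(sum(nrm^2))
    if (len < 1e-12) {
      nrm <- V[k, ] - centroid
      len <- sqrt(sum(nrm^2))
    }
    nrm <- nrm / len
    if (sum(nrm * (V[k, ] - centroid)) < 0) nrm <- -nrm
    normals[k, ] <- nrm
  }
  normals
}

#' Sample a gray-level intensity profile along a normal
#'
#' Extracts `2 * ns + 1` samples centred on the surface point, protruding
#' both inside and outside the surface: sample `j` sits at
#' `point + (j - ns - 1) * step * normal` for `j = 1 .. 2*ns+1`, interpolated
#' cubically. With the default `ns = 2` the profile has length 5.
#'
#' @param vol a `prostasm_volume` (isotropic grid recommended).
#' @param point surface point (mm).
#' @param normal unit outward normal.
#' @param ns half-length in samples (default 2).
#' @param step sample spacing in mm (default: one voxel of `vol`).
#' @return numeric profile of length `2 * ns + 1` (inside first, outside
#'   last).
#' @export
sample_profile <- function(vol, point, normal, ns = 2,
                           step = min(vol$spacing)) {
  sample_profiles(vol, matrix(point, 1), matrix(normal, 1), ns, step)[1, ]
}

#' @rdname sample_profile
#' @param points,normals K x 3 matrices for batched extraction.
#' @return `sample_profiles` returns a K x (2*ns+1) matrix.
#' @export
sample_profiles <- function(vol, points, normals, ns = 2,
                            step = min(vol$spacing)) {
  stopifnot(is_volume(vol))
  offs <- (-ns):ns
  K <- nrow(points)
  qpts <- points[rep(seq_len(K), each = length(offs)), , drop = FALSE] +
    normals[rep(seq_len(K), each = length(offs)), , drop = FALSE] *
      rep(offs * step, K)
  vals <- sample_volume(vol, qpts, mode = "cubic")
  matrix(vals, nrow = K, byrow = TRUE)
}

#' Density-based (DBSCAN) filtering of intensity profiles
#'
#' Clusters profiles in profile space (Euclidean distance between
#' z-normalised profile vectors) with the classic DBSCAN algorithm and keeps
#' the largest cluster; noise points and minor clusters are reported as
#' outliers. When `eps` is not given it is chosen from the elbow of the
#' sorted k-distance curve (k = `min_pts`).
#'
#' @param profiles n x m matrix, one profile per row (n >= `min_pts`).
#' @param eps neighbourhood radius; `NULL` (default) for the k-distance
#'   elbow.
#' @param min_pts minimum neighbourhood size of a core point (default 8).
#' @return `list(inliers, outliers, labels, eps)`; `labels` has 0 for noise.
#' @export
filter_profiles_dbscan <- function(profiles, eps = NULL, min_pts = 8) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < min_pts)
    stop("need at least min_pts = ", min_pts, " profiles", call. = FALSE)
  if (!is.null(eps) && eps <= 0) stop("eps must be > 0", call. = FALSE)
  z <- t(apply(profiles, 1, function(p) {
    s <- sd(p)
    if (s < 1e-12) p * 0 else (p - mean(p)) / s
  }))
  if (is.null(eps)) {
    kd <- RANN::nn2(z, z, k = min(min_pts, n))$nn.dists[, min(min_pts, n)]
    kd <- sort(kd)
    if (max(kd) < 1e-9) {
      eps <- 0.5
    } else {
      # elbow: maximum discrete curvature of the sorted k-distance curve
      d2 <- diff(kd, differences = 2)
      elbow <- if (length(d2) > 0) which.max(d2) + 1L else length(kd)
      eps <- max(kd[elbow], quantile(kd, 0.5), 1e-6)
    }
  }
  labels <- dbscan_labels(z, eps, min_pts)
  if (all(labels == 0))
    stop("DBSCAN labelled every profile as noise; increase eps (used ",
         signif(eps, 4), ")", call. = FALSE)
  counts <- tabulate(labels)
  main <- which.max(counts)
  inliers <- which(labels == main)
  list(inliers = inliers, outliers = setdiff(seq_len(n), inliers),
       labels = labels, eps = eps)
}

# classic DBSCAN; neighbourhoods include the point itself
dbscan_labels <- function(x, eps, min_pts) {
  n <- nrow(x)
  nbr <- vector("list", n)
  # radius queries via a distance matrix; profile sets are small (10^3-10^4)
  d2 <- as.matrix(stats::dist(x))^2
  for (i in seq_len(n)) nbr[[i]] <- which(d2[i, ] <= eps^2)
  core <- vapply(nbr, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier) > 0) {
      expand <- frontier[core[frontier]]
      if (length(expand) == 0) break
      nxt <- unique(unlist(nbr[expand], use.names = FALSE))
      nxt <- nxt[labels[nxt] == 0L]
      labels[nxt] <- cl
      frontier <- nxt
    }
  }
  labels
}

#' Build a gray-level appearance model from profiles
#'
#' PCA of the (inlier) profile matrix: the mean profile plus eigenvectors /
#' eigenvalues of the profile covariance. The number of modes is capped at
#' `profile length - 1` and at the available rank; zero-variance directions
#' are dropped.
#'
#' @param profiles n x m matrix of inlier profiles (n >= 3).
#' @param max_modes optional cap on retained modes.
#' @return a `prostasm_appearance_model`: `g_mean`, `Wg` (m x q), `lambda_g`
#'   (q, decreasing), `n_profiles`.
#' @export
build_appearance_model <- function(profiles, max_modes = NULL) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  m <- ncol(profiles)
  if (n < 3) stop("need at least 3 profiles for an appearance model",
                  call. = FALSE)
  g_mean <- colMeans(profiles)
  Xc <- sweep(profiles, 2, g_mean)
  S <- crossprod(Xc) / (n - 1)
  eg <- eigen(S, symmetric = TRUE)
  tot <- sum(pmax(eg$values, 0))
  keep <- which(eg$values > max(1e-10 * tot, 1e-12))
  keep <- head(keep, m - 1L)
  if (!is.null(max_modes)) keep <- head(keep, max_modes)
  structure(list(g_mean = g_mean,
                 Wg = eg$vectors[, keep, drop = FALSE],
                 lambda_g = eg$values[keep],
                 n_profiles = n),
            class = "prostasm_appearance_model")
}

#' @export
print.prostasm_appearance_model <- function(x, ...) {
  cat(sprintf("<appearance model> profile length %d, %d mode(s), n = %d\n",
              length(x$g_mean), length(x$lambda_g), x$n_profiles))
  invisible(x)
}
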