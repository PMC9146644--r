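# Shared fixtures, all generated in code.

# analytic ball mask of radius r_mm centred in a grid
ball_mask <- function(r_mm = 10, spacing = c(1, 1, 3), margin = 4) {
  half <- r_mm + margin
  d <- as.integer(ceiling(2 * half / spacing) + 1)
  ctr <- (d - 1) * spacing / 2
  gx <- (seq_len(d[1]) - 1) * spacing[1] - ctr[1]
  gy <- (seq_len(d[2]) - 1) * spacing[2] - ctr[2]
  gz <- (seq_len(d[3]) - 1) * spacing[3] - ctr[3]
  dx <- rep(gx, times = d[2] * d[3])
  dy <- rep(rep(gy, each = d[1]), times = d[3])
  dz <- rep(gz, each = d[1] * d[2])
  as_mask(array(as.integer(dx^2 + dy^2 + dz^2 <= r_mm^2), d), spacing)
}

# axis-aligned ellipsoid mask on an isotropic grid
ellipsoid_mask <- function(radii = c(30, 20, 20), spacing = 1, margin = 4) {
  half <- radii + margin
  d <- as.integer(ceiling(2 * half / spacing) + 1)
  ctr <- (d - 1) * spacing / 2
  gx <- (seq_len(d[1]) - 1) * spacing - ctr[1]
  gy <- (seq_len(d[2]) - 1) * spacing - ctr[2]
  gz <- (seq_len(d[3]) - 1) * spacing - ctr[3]
  dx <- rep(gx, times = d[2] * d[3])
  dy <- rep(rep(gy, each = d[1]), times = d[3])
  dz <- rep(gz, each = d[1] * d[2])
  inside <- (dx / radii[1])^2 + (dy / radii[2])^2 + (dz / radii[3])^2 <= 1
  as_mask(array(as.integer(inside), d), rep(spacing, 3))
}

# uniformly distributed points on a sphere (deterministic under seed)
sphere_cloud <- function(n = 800, r = 10, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  u * r
}

# small random blob masks for metric oracles
random_mask <- function(d = c(9, 9, 9), spacing = c(1, 1, 2), p = 0.5,
                        seed = 1) {
  set.seed(seed)
  ctr <- (d - 1) * spacing / 2
  n_seed <- sample(1:3, 1)
  arr <- array(FALSE, d)
  co <- arrayInd(seq_len(prod(d)), d)
  pos <- sweep(co - 1, 2, spacing, `*`)
  for (s in seq_len(n_seed)) {
    c0 <- runif(3, 0.25, 0.75) * (d - 1) * spacing
    r0 <- runif(1, 1.5, 4)
    arr <- arr | array(rowSums(sweep(pos, 2, c0, `-`)^2) <= r0^2, d)
  }
  as_mask(array(as.integer(arr), d), spacing)
}

# brute-force hd95 on small masks (independent of the package EDT/kNN path)
brute_hd95 <- function(a, b) {
  pa <- surface_points_mm(a)
  pb <- surface_points_mm(b)
  d_ab <- apply(pa, 1, function(p) min(sqrt(colSums((t(pb) - p)^2))))
  d_ba <- apply(pb, 1, function(p) min(sqrt(colSums((t(pa) - p)^2))))
  max(quantile(d_ab, 0.95, names = FALSE, type = 7),
      quantile(d_ba, 0.95, names = FALSE, type = 7))
}

brute_hausdorff <- function(a, b) {
  pa <- surface_points_mm(a)
  pb <- surface_points_mm(b)
  max(max(apply(pa, 1, function(p) min(sqrt(colSums((t(pb) - p)^2))))),
      max(apply(pb, 1, function(p) min(sqrt(colSums((t(pa) - p)^2))))))
}

# brute-force ray/triangle oracle: plane intersection + barycentric solve
oracle_ray_tri <- function(origin, direction, tri) {
  d <- direction / sqrt(sum(direction^2))
  e1 <- tri[2, ] - tri[1, ]
  e2 <- tri[3, ] - tri[1, ]
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  denom <- sum(n * d)
  if (abs(denom) < 1e-12) return(NULL)
  t <- sum(n * (tri[1, ] - origin)) / denom
  if (t < 0) return(NULL)
  p <- origin + t * d
  # solve p - v0 = u*e1 + v*e2 by least squares (exact: p lies in the plane)
  A <- cbind(e1, e2)
  uv <- solve(crossprod(A), crossprod(A, p - tri[1, ]))
  u <- uv[1]; v <- uv[2]
  if (u < 0 || v < 0 || u + v > 1) return(NULL)
  list(t = t, u = u, v = v)
}

# standard isotropic cohort settings for shape-recovery experiments
recovery_phantom_spec <- function() {
  phantom_spec(grid_shape = c(192, 192, 144), grid_spacing = c(0.5, 0.5, 0.5))
}
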