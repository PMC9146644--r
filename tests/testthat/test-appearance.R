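test_that("sphere normals are radial, unit length and outward", {
  pts <- sphere_cloud(n = 4000, r = 10, seed = 4)
  mesh <- alpha_triangulate(pts, alpha = 50)
  sh <- prostasm:::as_shape(pts)
  nrm <- surface_normals(sh, mesh)
  expect_equal(sqrt(rowSums(nrm^2)), rep(1, nrow(pts)), tolerance = 1e-9)
  radial <- pts / sqrt(rowSums(pts^2))
  ang <- acos(pmin(1, rowSums(nrm * radial))) * 180 / pi
  expect_lt(quantile(ang, 0.99, names = FALSE), 2)
  expect_lt(max(ang), 3)
  expect_true(all(rowSums(nrm * radial) > 0))  # outward
})

test_that("profiles have the documented length and sampling geometry", {
  vol <- as_volume(array(7, c(20, 20, 20)), spacing = c(0.5, 0.5, 0.5))
  p <- sample_profile(vol, c(5, 5, 5), c(1, 0, 0), ns = 2, step = 0.5)
  expect_length(p, 5)                       # length = 2 * ns + 1 with ns = 2
  expect_true(all(abs(p - 7) < 1e-9))        # constant volume
  # linear ramp: cubic interpolation is exact, increments = step * slope
  d <- c(30, 30, 30)
  ramp <- as_volume(array(rep(3 * (0:(d[1] - 1)) * 0.5, times = prod(d[2:3])),
                          d), spacing = rep(0.5, 3))
  pr <- sample_profile(ramp, c(7, 7, 7), c(1, 0, 0), ns = 2, step = 0.5)
  expect_equal(diff(pr), rep(0.5 * 3, 4), tolerance = 1e-9)
})

test_that("profile extraction is linear in the image", {
  set.seed(8)
  d <- c(16, 16, 16)
  v1 <- as_volume(array(rnorm(prod(d)), d), spacing = rep(0.5, 3))
  v2 <- as_volume(array(rnorm(prod(d)), d), spacing = rep(0.5, 3))
  combo <- as_volume(2 * v1$data - 3 * v2$data, v1$spacing)
  pts <- matrix(runif(15, 2, 5), 5, 3)
  nrms <- matrix(rnorm(15), 5, 3)
  nrms <- nrms / sqrt(rowSums(nrms^2))
  pc <- sample_profiles(combo, pts, nrms, ns = 2, step = 0.5)
  p1 <- sample_profiles(v1, pts, nrms, ns = 2, step = 0.5)
  p2 <- sample_profiles(v2, pts, nrms, ns = 2, step = 0.5)
  expect_equal(pc, 2 * p1 - 3 * p2, tolerance = 1e-9)
})

test_that("DBSCAN flags planted outlier profiles and nothing else", {
  set.seed(5)
  base <- matrix(rnorm(50 * 5, sd = 0.05), 50, 5) +
    matrix(rep(c(10, 30, 80, 120, 140), each = 50), 50, 5)
  planted <- base[1:5, ] + matrix(rnorm(25, mean = 40, sd = 10), 5, 5)
  prof <- rbind(base, planted)
  res <- filter_profiles_dbscan(prof, min_pts = 8)
  expect_setequal(res$outliers, 51:55)
  expect_length(res$inliers, 50)
  # filtering never increases the profile count and is deterministic
  res2 <- filter_profiles_dbscan(prof, min_pts = 8)
  expect_identical(res$labels, res2$labels)
  expect_lte(length(res$inliers), nrow(prof))
})

test_that("DBSCAN edge cases behave as documented", {
  same <- matrix(5, 20, 5)
  res <- filter_profiles_dbscan(same, min_pts = 8)
  expect_length(res$inliers, 20)
  expect_error(filter_profiles_dbscan(same, eps = 0), "> 0")
  expect_error(filter_profiles_dbscan(same[1:3, ], min_pts = 8),
               "at least")
})

test_that("appearance PCA recovers a planted rank-1 structure", {
  set.seed(9)
  g0 <- c(100, 110, 125, 138, 150)
  dirn <- c(1, 2, 0, -2, -1); dirn <- dirn / sqrt(sum(dirn^2))
  prof <- t(vapply(rnorm(40, sd = 6), function(t) g0 + t * dirn,
                   numeric(5)))
  am <- build_appearance_model(prof)
  expect_gt(abs(sum(am$Wg[, 1] * dirn)), 0.99)
  expect_lte(ncol(am$Wg), 4)               # q <= n - 1 for length-5 profiles
  expect_true(all(am$lambda_g > 0))
  # identical profiles: mean equals the profile, no modes survive
  am0 <- build_appearance_model(matrix(rep(g0, 5), 5, byrow = TRUE))
  expect_equal(am0$g_mean, g0)
  expect_identical(length(am0$lambda_g), 0L)
  expect_error(build_appearance_model(prof[1:2, ]), "at least 3")
})

test_that("the mean profile crosses the boundary monotonically on phantoms", {
  ph <- make_phantom(phantom_spec(seed = 12, noise_sd = 2,
                                  bias_range = c(1, 1)))
  vi <- resample_isotropic(ph$volume, 0.5)
  mi <- resample_isotropic(ph$mask, 0.5)
  sh <- extract_corresponded_vertices(mi)
  mesh <- mesh_from_vertices(sh, alpha = 30)
  nrm <- surface_normals(sh, mesh, max_dist = 5)
  prof <- sample_profiles(vi, prostasm:::shape_matrix(sh), nrm, ns = 2,
                          step = 0.5)
  g_mean <- colMeans(prof)
  # interior is bright: the profile decreases from inside to outside
  expect_true(all(diff(g_mean) < 0))
})
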