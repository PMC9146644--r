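test_that("ellipsoid fit recovers generator parameters on a discretised ellipsoid", {
  m <- ellipsoid_mask(radii = c(30, 20, 20), spacing = 1)
  for (method in c("moments", "surface-ls")) {
    fit <- fit_ellipsoid(m, method = method)
    ctr_true <- (dim(m$data) - 1) / 2
    expect_true(all(abs(fit$centre - ctr_true) <= 1))
    expect_true(all(abs(fit$axis_radii - c(30, 20, 20)) / c(30, 20, 20)
                    < 0.05))
  }
})

test_that("sphere symmetry collapses the key points onto the centre", {
  m <- ball_mask(r_mm = 12, spacing = c(1, 1, 1))
  fit <- fit_ellipsoid(m)
  expect_lt(abs(fit$radii[1] - fit$radii[3]), 0.5)
  expect_lt(fit$c_xy, 1.5)  # sqrt(rmax^2 - rmin^2) ~ 0 for a sphere
  expect_true(all(abs(fit$key_points["F_xy+", ] - fit$key_points["F_xy-", ])
                  < 1.5))
})

test_that("degenerate masks are rejected by the fit", {
  single <- array(0L, c(8, 8, 8)); single[4, 4, 4] <- 1L
  expect_error(fit_ellipsoid(as_mask(single)), "surface voxels")
  slab <- array(0L, c(12, 12, 5)); slab[3:10, 3:10, 3] <- 1L
  expect_error(fit_ellipsoid(as_mask(slab)), "coplanar|ellipsoid")
})

test_that("correspondence extraction is deterministic with the documented K", {
  m <- resample_isotropic(make_phantom(phantom_spec(seed = 2),
                                       mask_only = TRUE)$mask, 0.5)
  s1 <- extract_corresponded_vertices(m)
  s2 <- extract_corresponded_vertices(m)
  expect_identical(unclass(s1), unclass(s2))
  expect_identical(nrow(s1), prostasm:::ray_config_K(ray_config()))
  expect_error(extract_corresponded_vertices(
    make_phantom(phantom_spec(seed = 2), mask_only = TRUE)$mask),
    "isotropic")
})

test_that("centre-sourced vertices of a sphere sit at the radius", {
  m <- resample_isotropic(ball_mask(r_mm = 15, spacing = c(1, 1, 3),
                                    margin = 6), 0.5)
  sh <- extract_corresponded_vertices(m)
  fit <- fit_ellipsoid(m)
  centre_block <- unclass(sh)[1:56, 1:3]  # source 1 = centre
  r_hat <- sqrt(rowSums(sweep(centre_block, 2, fit$centre)^2))
  expect_true(all(abs(r_hat - 15) <= 1))
})

test_that("a detached blob beyond the gland captures the farthest-hit vertex", {
  m <- resample_isotropic(ball_mask(r_mm = 10, spacing = c(1, 1, 1),
                                    margin = 14), 0.5)
  d <- dim(m$data)
  ctr <- round(d / 2)
  arr <- m$data
  # blob along +x, 20 mm from the centre (beyond the 10 mm surface)
  arr[(ctr[1] + 40):(ctr[1] + 44), (ctr[2] - 2):(ctr[2] + 2),
      (ctr[3] - 2):(ctr[3] + 2)] <- 1L
  noisy <- as_mask(arr, m$spacing, m$origin)
  sh_clean <- extract_corresponded_vertices(m)
  sh_noisy <- extract_corresponded_vertices(noisy)
  d_clean <- max(sqrt(rowSums(sweep(unclass(sh_clean)[, 1:3], 2,
                                    colMeans(unclass(sh_clean)[, 1:3]))^2)))
  d_noisy <- max(sqrt(rowSums(sweep(unclass(sh_noisy)[, 1:3], 2,
                                    colMeans(unclass(sh_clean)[, 1:3]))^2)))
  expect_gt(d_noisy, d_clean + 5)  # some vertex landed on the blob
})

test_that("alignment recovers translations and rotations exactly", {
  m <- resample_isotropic(make_phantom(phantom_spec(seed = 5),
                                       mask_only = TRUE)$mask, 0.5)
  sh <- extract_corresponded_vertices(m)
  # identity
  self <- align_shape(sh, sh)
  expect_lt(abs(self$transform$theta_z), 1e-9)
  expect_lt(abs(self$transform$theta_y), 1e-9)
  # pure translation
  tr <- as_shape(unclass(sh)[, 1:3] + rep(c(5, -3, 2), each = nrow(sh)))
  al <- align_shape(tr, sh)
  expect_lt(max(abs(unclass(al$shape)[, 1:3] - unclass(sh)[, 1:3])), 1e-9)
  expect_lt(abs(al$transform$theta_z), 1e-9)
  # 20 degree rotation about z
  th <- 20 * pi / 180
  ctr <- colMeans(unclass(sh)[, 1:3])
  R <- prostasm:::rot_z(th)
  rot <- as_shape(sweep(sweep(unclass(sh)[, 1:3], 2, ctr) %*% t(R), 2, ctr,
                        `+`))
  al2 <- align_shape(rot, sh)
  expect_equal(al2$transform$theta_z, -th, tolerance = 1e-6)
  rms <- sqrt(mean((unclass(al2$shape)[, 1:3] - unclass(sh)[, 1:3])^2))
  expect_lt(rms, 0.1)
  # round trip through the inverse alignment
  back <- invert_alignment(al2$shape, al2$transform)
  expect_lt(max(abs(unclass(back)[, 1:3] - unclass(rot)[, 1:3])), 1e-6)
  expect_error(align_shape(as_shape(matrix(0, 5, 3)), sh), "vertex counts")
})

test_that("shape PCA satisfies its rank and reconstruction guarantees", {
  m <- resample_isotropic(make_phantom(phantom_spec(seed = 6),
                                       mask_only = TRUE)$mask, 0.5)
  sh <- extract_corresponded_vertices(m)
  # identical shapes: no variance, mean equals the shape
  sm0 <- build_shape_model(list(sh, sh, sh))
  expect_identical(length(sm0$lambda), 0L)
  expect_equal(sm0$x_mean, as.numeric(unclass(sh)[, 1:3]), tolerance = 1e-9)
  expect_error(build_shape_model(list(sh, sh)), "at least 3")
  # random perturbed cohort: full-variance rank bound t <= n - 1
  set.seed(3)
  shapes <- lapply(1:6, function(i)
    as_shape(unclass(sh)[, 1:3] + matrix(rnorm(3 * nrow(sh), 0, 0.5),
                                         ncol = 3)))
  sm1 <- build_shape_model(shapes, variance = 1.0)
  expect_lte(length(sm1$lambda), 5L)
  # with all modes, training shapes reconstruct to numerical precision
  X <- t(vapply(shapes, prostasm:::flatten_shape, numeric(3 * nrow(sh))))
  for (i in c(1, 4)) {
    b <- crossprod(sm1$Ws, X[i, ] - sm1$x_mean)
    rec <- sm1$x_mean + sm1$Ws %*% b
    expect_lt(sqrt(mean((rec - X[i, ])^2)), 1e-6)
  }
  # eigenvectors orthonormal, eigenvalues decreasing
  expect_equal(crossprod(sm1$Ws), diag(length(sm1$lambda)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(sm1$lambda) <= 1e-9))
})

test_that("a two-mode phantom cohort is recovered at 98% variance", {
  base <- recovery_phantom_spec()
  cohort <- make_cohort(30, base, seed = 1, keep = "mask")
  shapes <- lapply(cohort, function(m) extract_corresponded_vertices(m$mask))
  aligned <- shapes
  for (i in 2:30)
    aligned[[i]] <- align_shape(shapes[[i]], shapes[[1]])$shape
  sm <- build_shape_model(aligned, variance = 0.98)
  expect_identical(length(sm$lambda), 2L)
  # leading eigenvector tracks the dominant generating displacement field
  h <- 1
  sp <- base; sp$mode_amplitudes[5] <- h
  sn <- base; sn$mode_amplitudes[5] <- -h
  g <- function(s) as.numeric(unclass(extract_corresponded_vertices(
    make_phantom(s, mask_only = TRUE)$mask))[, 1:3])
  f <- (g(sp) - g(sn)) / (2 * h)
  expect_gt(abs(cor(f, sm$Ws[, 1])), 0.9)
  # retained-mode residual is within the 2% budget
  expect_gte(sm$variance_retained, 0.98)
})
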