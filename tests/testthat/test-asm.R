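# tiny deterministic appearance model for arithmetic checks
toy_amodel <- function() {
  g0 <- c(10, 20, 30, 40, 50)
  W <- qr.Q(qr(cbind(c(1, 1, 0, -1, -1), c(1, -1, 0, -1, 1))))
  structure(list(g_mean = g0, Wg = W, lambda_g = c(4, 1), n_profiles = 10),
            class = "prostasm_appearance_model")
}

test_that("profile cost is the eigenvalue-scaled quadratic form", {
  am <- toy_amodel()
  expect_equal(profile_cost(am$g_mean, am), 0)
  # deviation of one eigenvalue along the first mode scores exactly 1
  g1 <- am$g_mean + am$lambda_g[1] * am$Wg[, 1]
  expect_equal(profile_cost(g1, am), 1, tolerance = 1e-12)
  # sqrt scaling divides by standard deviations instead
  expect_equal(profile_cost(g1, am, eigen_scaling = "sqrt"),
               (am$lambda_g[1] / sqrt(am$lambda_g[1]))^2, tolerance = 1e-12)
  # invariance to out-of-span components
  ortho <- residuals(lm.fit(am$Wg, rnorm(5)))
  expect_equal(profile_cost(g1 + 5 * ortho, am), profile_cost(g1, am),
               tolerance = 1e-9)
  expect_error(profile_cost(1:4, am), "length")
})

test_that("movement follows the printed index arithmetic and its bounds", {
  am <- toy_amodel()
  ns_search <- 8
  # an extended profile whose best sub-profile sits at the first index
  ext <- rep(1000, 2 * (ns_search + 2) + 1)
  ext[1:5] <- am$g_mean
  expect_identical(
    prostasm:::movement_from_profile(ext, am, ns_search, 2, "linear"), -8)
  # centred best sub-profile gives zero movement
  ext2 <- rep(1000, 2 * (ns_search + 2) + 1)
  ext2[(ns_search + 1):(ns_search + 5)] <- am$g_mean
  expect_identical(
    prostasm:::movement_from_profile(ext2, am, ns_search, 2, "linear"), 0)
  # constant profile: all candidates tie, the damped tie-break stays put
  ext3 <- rep(30, 2 * (ns_search + 2) + 1)
  expect_identical(
    prostasm:::movement_from_profile(ext3, am, ns_search, 2, "linear"), 0)
})

test_that("a planted edge displaced by +3 samples is found", {
  # appearance model trained on centred edges of a bright-inside boundary
  edge <- function(centre_offset, step = 0.5) {
    x <- ((-2):2 - centre_offset) * step
    150 - 80 * pnorm(x, sd = 0.7)
  }
  set.seed(2)
  train <- t(vapply(rnorm(30, 0, 0.1), edge, numeric(5)))
  am <- build_appearance_model(train)
  d <- c(64, 64, 64)
  edge_x <- 20.75  # boundary plane, mm
  vals <- 150 - 80 * pnorm(((0:(d[1] - 1)) * 0.5 - edge_x), sd = 0.7)
  vol <- as_volume(array(rep(vals, times = prod(d[2:3])), d),
                   spacing = rep(0.5, 3))
  # current point sits 3 samples (1.5 mm) inside the true boundary
  mv <- best_movement(vol, c(edge_x - 1.5, 16, 16), c(1, 0, 0), am,
                      ns_search = 8)
  expect_identical(mv, 3)
  expect_lte(abs(mv), 8)
})

test_that("shape constraint clamps, reconstructs and is idempotent", {
  base <- recovery_phantom_spec()
  cohort <- make_cohort(8, base, seed = 3, keep = "mask")
  shapes <- lapply(cohort, function(m) extract_corresponded_vertices(m$mask))
  aligned <- shapes
  for (i in 2:8) aligned[[i]] <- align_shape(shapes[[i]], shapes[[1]])$shape
  sm <- build_shape_model(aligned)
  mean_sh <- mean_shape(sm)
  # mean maps to itself with zero coordinates
  c0 <- constrain_shape(mean_sh, sm, m = 2)
  expect_true(all(abs(c0$b) < 1e-9))
  expect_equal(unclass(c0$shape)[, 1:3], unclass(mean_sh)[, 1:3],
               tolerance = 1e-9)
  # within-bounds shapes are reproduced exactly
  w1 <- prostasm:::unflatten_shape(sm$x_mean + 0.5 * 2 * sm$lambda[1] *
                                     sm$Ws[, 1])
  c1 <- constrain_shape(prostasm:::as_shape(w1), sm, m = 2)
  expect_false(any(c1$clamped))
  expect_equal(unclass(c1$shape)[, 1:3], w1, tolerance = 1e-9)
  # out-of-bounds coordinates are clamped to m * lambda
  w2 <- prostasm:::unflatten_shape(sm$x_mean + 2 * 2 * sm$lambda[1] *
                                     sm$Ws[, 1])
  c2 <- constrain_shape(prostasm:::as_shape(w2), sm, m = 2)
  expect_true(c2$clamped[1])
  expect_equal(c2$b[1], 2 * sm$lambda[1], tolerance = 1e-9)
  # idempotence
  c3 <- constrain_shape(c2$shape, sm, m = 2)
  expect_equal(unclass(c3$shape)[, 1:3], unclass(c2$shape)[, 1:3],
               tolerance = 1e-9)
  # m = 0 collapses everything onto the mean
  cm0 <- constrain_shape(prostasm:::as_shape(w2), sm, m = 0)
  expect_equal(as.numeric(unclass(cm0$shape)[, 1:3]), sm$x_mean,
               tolerance = 1e-9)
  expect_error(constrain_shape(prostasm:::as_shape(matrix(0, 4, 3)), sm, 2),
               "K")
})

test_that("presets follow the ablation table and the default follows the text", {
  p <- asm_preset("ASM-2")
  expect_identical(c(p$iterations, p$ns_search), c(2L, 8L))
  expect_identical(p$m, 1)
  p4 <- asm_preset("ASM-4")
  expect_identical(p4$m, 3)
  expect_error(asm_preset("ASM-9"), "unknown")
  d <- asm_config()
  expect_identical(c(d$iterations, d$ns_search), c(2L, 8L))
  expect_identical(d$m, 2)
  expect_error(asm_config(ns_search = 1, ns_model = 2), "ns_search")
})

test_that("zero iterations return the input and refinement is stable at the truth", {
  ph <- make_phantom(phantom_spec(seed = 41))
  vi <- resample_isotropic(ph$volume, 0.5)
  mi <- resample_isotropic(ph$mask, 0.5)
  sh <- extract_corresponded_vertices(mi)
  cohort <- make_cohort(6, phantom_spec(), seed = 17)
  arch <- build_models(lapply(cohort, `[[`, "volume"),
                       lapply(cohort, `[[`, "mask"),
                       bias_correction = FALSE, standardize = FALSE)
  r0 <- refine(vi, sh, arch$shape_model, arch$appearance_models,
               asm_config(iterations = 0))
  expect_equal(unclass(r0)[, 1:3], unclass(sh)[, 1:3])
  # starting at the truth, refinement stays within 1.5 mm mean vertex error
  r2 <- refine(vi, sh, arch$shape_model, arch$appearance_models,
               asm_config())
  mean_d <- mean(sqrt(rowSums((unclass(r2)[, 1:3] - unclass(sh)[, 1:3])^2)))
  expect_lt(mean_d, 1.5)
  # plausibility guarantee: |b_i| <= m * lambda_i in the model frame
  b <- attr(r2, "b")
  expect_true(all(abs(b) <= 2 * arch$shape_model$lambda + 1e-9))
})
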