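test_that("undeformed noiseless phantom is the exact discretised ellipsoid", {
  spec <- phantom_spec(mode_amplitudes = rep(0, 8), noise_sd = 0,
                      bias_range = c(1, 1))
  ph <- make_phantom(spec)
  v_analytic <- 4 / 3 * pi * prod(spec$base_radii)
  expect_lt(abs(mask_volume_mm3(ph$mask) - v_analytic) / v_analytic, 0.05)
  # interior/exterior intensities separate cleanly without noise or bias
  expect_gt(mean(ph$volume$data[ph$mask$data == 1]),
            mean(ph$volume$data[ph$mask$data == 0]))
})

test_that("phantom generation is deterministic and validates its spec", {
  a <- make_phantom(phantom_spec(seed = 9))
  b <- make_phantom(phantom_spec(seed = 9))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  c_ <- make_phantom(phantom_spec(seed = 10))
  expect_false(identical(a$volume$data, c_$volume$data))
  expect_error(phantom_spec(base_radii = c(0, 10, 10)), "positive")
  expect_error(phantom_spec(noise_sd = -1), ">= 0")
  expect_error(make_phantom(phantom_spec(base_radii = c(80, 17, 15))),
               "exceeds")
})

test_that("phantom masks are a single simply connected component", {
  for (s in 1:3) {
    co <- make_cohort(2, phantom_spec(), seed = s, keep = "mask")
    for (m in co) {
      expect_identical(n_components(m$mask, 26), 1L)
      filled <- fill_holes(m$mask)
      expect_identical(filled$data, m$mask$data)  # no interior cavities
    }
  }
})

test_that("cohort weights follow the requested mode variances", {
  md <- default_cohort_mode_sd()
  co <- make_cohort(30, phantom_spec(), mode_sd = md, seed = 5, keep = "mask")
  W <- t(vapply(co, `[[`, numeric(8), "weights"))
  act <- which(md > 0)
  expect_identical(which(colSums(abs(W)) > 0), act)
  emp <- apply(W[, act], 2, var)
  expect_true(all(abs(emp - md[act]^2) / md[act]^2 < 0.30))
  # zero mode_sd gives congruent members
  co0 <- make_cohort(3, phantom_spec(), mode_sd = rep(0, 8), seed = 5,
                     keep = "mask")
  expect_identical(co0[[1]]$mask$data, co0[[2]]$mask$data)
  expect_error(make_cohort(1, phantom_spec()), "at least 2")
  # reproducibility
  co2 <- make_cohort(30, phantom_spec(), mode_sd = md, seed = 5,
                     keep = "mask")
  expect_identical(co2[[7]]$mask$data, co[[7]]$mask$data)
})

test_that("mask corruption is calibrated, seeded and monotone in severity", {
  ph <- make_phantom(phantom_spec(seed = 21), mask_only = TRUE)
  expect_identical(corrupt_mask(ph$mask, 0, seed = 1)$data, ph$mask$data)
  c1 <- corrupt_mask(ph$mask, 0.3, seed = 11)
  expect_identical(corrupt_mask(ph$mask, 0.3, seed = 11)$data, c1$data)
  d <- dsc(c1, ph$mask)
  expect_gte(d, 0.75)
  expect_lte(d, 0.95)
  expect_error(corrupt_mask(as_mask(array(0L, c(4, 4, 4))), 0.5), "empty")
  expect_error(corrupt_mask(ph$mask, 2), "\\[0, 1\\]")
})

test_that("mean overlap decreases from mild to maximal corruption", {
  ph <- make_phantom(phantom_spec(seed = 22), mask_only = TRUE)
  d_mild <- vapply(1:20, function(s) dsc(corrupt_mask(ph$mask, 0.1, s),
                                         ph$mask), numeric(1))
  d_max <- vapply(1:20, function(s) dsc(corrupt_mask(ph$mask, 1, s),
                                        ph$mask), numeric(1))
  expect_lt(mean(d_max), mean(d_mild))
})
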