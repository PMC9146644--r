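# phantom with a known multiplicative polynomial field for bias oracles
biased_phantom <- function(range = c(0.8, 1.2), seed = 5) {
  spec <- phantom_spec(noise_sd = 2, bias_range = c(1, 1), seed = seed)
  ph <- make_phantom(spec)
  d <- dim(ph$volume$data)
  cx <- seq(-1, 1, length.out = d[1])
  cy <- seq(-1, 1, length.out = d[2])
  cz <- seq(-1, 1, length.out = d[3])
  f <- outer(outer(0.6 * cx + 0.4 * cx^2, 0.5 * cy, `+`), 0.3 * cz + 0.2 * cz^2, `+`)
  f <- (f - min(f)) / (max(f) - min(f)) * diff(range) + range[1]
  list(u = ph$volume,
       v = as_volume(ph$volume$data * f, ph$volume$spacing, ph$volume$origin),
       field = f, mask = ph$mask)
}

test_that("bias correction is near-identity on field-free volumes", {
  ph <- make_phantom(phantom_spec(bias_range = c(1, 1), seed = 8))
  res <- correct_bias_field(ph$volume)
  fg <- ph$mask$data == 1
  rel <- abs(res$volume$data[fg] - ph$volume$data[fg]) /
    pmax(ph$volume$data[fg], 1)
  expect_lt(median(rel), 0.01)
  expect_true(all(res$bias$field > 0))
  expect_equal(mean(res$bias$field[ph$volume$data >
                                   prostasm:::otsu_threshold(ph$volume$data)]),
               1, tolerance = 0.05)
})

test_that("bias correction halves the known-field non-uniformity", {
  bp <- biased_phantom()
  res <- correct_bias_field(bp$v)
  # evaluate inside the organ, where the uncorrupted image is homogeneous
  # and the ratio to the known ground truth isolates the residual field
  fg <- bp$mask$data == 1
  cv <- function(x) sd(x) / mean(x)
  cv_in <- cv((bp$v$data / pmax(bp$u$data, 1e-6))[fg])
  cv_out <- cv((res$volume$data / pmax(bp$u$data, 1e-6))[fg])
  expect_lt(cv_out, 0.5 * cv_in)
})

test_that("bias correction rejects invalid inputs", {
  neg <- as_volume(array(c(-1, rep(1, 7)), c(2, 2, 2)))
  expect_error(correct_bias_field(neg), "non-negative")
  expect_error(correct_bias_field(as_volume(array(0, c(4, 4, 4)))),
               "all-zero")
})

test_that("the standard scale averages affinely mapped landmarks", {
  ph <- make_phantom(phantom_spec(seed = 31))
  v <- ph$volume
  # identical volumes: standard positions equal either volume's mapping
  sc <- learn_standard_scale(list(v, v))
  lm_v <- prostasm:::volume_landmarks(v, sc$landmark_percentiles)
  rng <- attr(lm_v, "prange")
  mapped <- (lm_v - rng[1]) / (rng[2] - rng[1]) * 4095
  expect_equal(unname(sc$standard_positions), as.numeric(mapped),
               tolerance = 1e-9)
  # V and 2V map to identical landmarks (affine pre-mapping removes scale)
  v2 <- as_volume(2 * v$data, v$spacing, v$origin)
  sc2 <- learn_standard_scale(list(v, v2))
  expect_equal(sc2$standard_positions, sc$standard_positions,
               tolerance = 1e-6)
  expect_error(learn_standard_scale(list()), "at least 2")
  const <- as_volume(array(7, c(6, 6, 6)))
  expect_error(learn_standard_scale(list(const, const)), "histogram")
})

test_that("standardisation hits the scale, is idempotent and monotone", {
  vols <- lapply(1:4, function(s) make_phantom(phantom_spec(seed = s))$volume)
  sc <- learn_standard_scale(vols)
  fresh <- make_phantom(phantom_spec(seed = 99))$volume
  std <- standardize_intensity(fresh, sc)
  lm_std <- prostasm:::volume_landmarks(std, sc$landmark_percentiles)
  expect_true(all(abs(lm_std - sc$standard_positions) < 1))
  # idempotence within one intensity unit
  std2 <- standardize_intensity(std, sc)
  lm_std2 <- prostasm:::volume_landmarks(std2, sc$landmark_percentiles)
  expect_true(all(abs(lm_std2 - as.numeric(lm_std)) < 1))
  # monotone: mapping never inverts intensity order
  set.seed(1)
  idx <- sample(length(fresh$data), 4000)
  ord <- order(fresh$data[idx])
  expect_true(all(diff(std$data[idx][ord]) > -1e-9))
  # a volume already on the scale maps to itself
  lm_f <- prostasm:::volume_landmarks(fresh, sc$landmark_percentiles)
  sc_self <- sc
  sc_self$standard_positions <- as.numeric(lm_f)
  self <- standardize_intensity(fresh, sc_self)
  expect_equal(self$data, fresh$data, tolerance = 1e-9)
  expect_error(standardize_intensity(as_volume(array(1, c(5, 5, 5))), sc),
               "histogram")
})

test_that("standard scales serialise to JSON and back", {
  vols <- lapply(1:2, function(s) make_phantom(phantom_spec(seed = s))$volume)
  sc <- learn_standard_scale(vols)
  p <- tempfile(fileext = ".json")
  save_standard_scale(sc, p)
  sc2 <- load_standard_scale(p)
  expect_equal(sc2$standard_positions, sc$standard_positions)
  expect_equal(sc2$landmark_percentiles, sc$landmark_percentiles)
})
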