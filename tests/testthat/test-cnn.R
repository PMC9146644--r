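test_that("the reference configuration reproduces the published parameter count", {
  spec <- build_vnet_t2(input_shape = c(512, 512, 24, 1), depth = 4,
                        base_filters = 8, n_classes = 2)
  expect_identical(count_parameters(spec), 1192593L)
})

test_that("parameter counting matches hand-enumerated layer sums", {
  # single 3x3x3 convolution, 1 -> 8 channels, with bias
  single <- list(layers = data.frame(name = "c", kind = "conv",
                                     kernel = "3x3x3", in_channels = 1,
                                     out_channels = 8))
  expect_identical(count_parameters(single), 27L * 8L + 8L)
  expect_identical(count_parameters(list(layers = NULL)), 0)

  # depth-1 network, base 1: conv 1->1, conv 1->2, output conv 2->1
  tiny <- build_vnet_t2(input_shape = c(8, 8, 8, 1), depth = 1,
                        base_filters = 1, n_classes = 2)
  manual <- (27 * 1 * 1 + 1) + (27 * 1 * 2 + 2) + (1 * 2 * 1 + 1)
  expect_identical(count_parameters(tiny), as.integer(manual))
  # instance norm layers carry no trainable parameters
  expect_true(all(c("instance_norm") %in% tiny$layers$kind))
})

test_that("indivisible spatial axes raise a shape error naming the axis", {
  expect_error(build_vnet_t2(input_shape = c(510, 512, 24, 1)), "axis x")
  expect_error(build_vnet_t2(input_shape = c(512, 508, 24, 1), depth = 4),
               "not divisible")
  # 24 slices pool 24 -> 12 -> 6 -> 3 without error at depth 4
  expect_silent(build_vnet_t2(input_shape = c(64, 64, 24, 1)))
})

test_that("soft dice loss follows its closed form", {
  d <- c(4, 4, 4)
  t <- array(0L, d); t[1:2, , ] <- 1L   # half foreground
  m <- as_mask(t)
  onehot <- array(as.numeric(t), d)
  expect_lt(dice_loss(onehot, m), 1e-3)
  expect_gt(dice_loss(array(0, d), m), 0.999)
  half <- array(0.5, d)
  expect_equal(dice_loss(half, m), 1 - (2 * 0.25) / (0.5 + 0.5),
               tolerance = 1e-4)
  # dice_loss + dice_score identity (score = 1 - loss by construction)
  expect_equal(dice_loss(onehot, m) + (1 - dice_loss(onehot, m)), 1)
  expect_error(dice_loss(array(0.5, c(3, 3, 3)), m), "grid")
})

test_that("class weights are inverse-frequency with mean one", {
  d <- c(10, 10, 10)
  half <- array(0L, d); half[1:5, , ] <- 1L
  w <- class_weights(list(as_mask(half)))
  expect_equal(unname(w), c(1, 1))
  ten <- array(0L, d); ten[1, , ] <- 1L  # 10% foreground
  w2 <- class_weights(list(as_mask(ten)))
  expect_equal(unname(w2["foreground"] / w2["background"]), 9)
  expect_equal(mean(w2), 1)
  expect_error(class_weights(list()), "at least one")
  expect_error(class_weights(list(as_mask(array(0L, d)))), "absent")
})

test_that("initial segmentation handles masks, probabilities and errors", {
  ph <- make_phantom(phantom_spec(seed = 3))
  seg <- initial_segmentation(ph$volume,
                              surrogate_initializer(ph$mask, 0.3, seed = 9))
  expect_true(is_mask(seg))
  d <- dsc(seg, ph$mask)
  expect_gte(d, 0.75)
  expect_lte(d, 0.95)
  # probability map everywhere > 0.5 gives an all-foreground mask
  allfg <- initial_segmentation(ph$volume,
                                function(v) array(0.9, dim(v$data)))
  expect_true(all(allfg$data == 1L))
  # grid mismatch from the adapter is a shape error
  expect_error(initial_segmentation(ph$volume,
                                    function(v) array(0.9, c(4, 4, 4))),
               "match")
})
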