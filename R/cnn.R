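#' Build the VNet-T2 architecture specification
#'
#' Constructs a declarative layer list for the 3D encoder-decoder used to
#' produce initial prostate segmentations, in the 3D-UNet Keras lineage:
#' each encoder level applies two 3x3x3 convolutions (with `f` and `2f`
#' filters, `f = base_filters * 2^level`), each followed by instance
#' normalisation (no trainable affine parameters), then 2x2x2 max pooling;
#' the decoder mirrors the encoder with transposed convolutions (kernel
#' equal to the pool size, filter count equal to the incoming channels),
#' concatenation with the skip connection, and two convolutions at the skip
#' level's channel count; a final 1x1x1 convolution produces a single
#' sigmoid foreground channel for the two-class problem (or `n_classes`
#' softmax channels otherwise). The layer list fully determines the
#' trainable-parameter count without allocating any weights.
#'
#' Pooling along z halves the axis only while it remains even, so thin
#' volumes (e.g. 24 slices) can be processed at their original size.
#'
#' @param input_shape `(X, Y, Z, channels)`; X and Y must be divisible by 2
#'   at every pooling level.
#' @param depth number of encoder levels (default 4).
#' @param base_filters filters of the first convolution (default 8).
#' @param n_classes number of classes (default 2, encoded as one sigmoid
#'   channel).
#' @return a `prostasm_network_spec` with a `layers` data frame
#'   (name, kind, kernel, in_channels, out_channels).
#' @export
build_vnet_t2 <- function(input_shape = c(512, 512, 24, 1), depth = 4,
                          base_filters = 8, n_classes = 2) {
  stopifnot(depth >= 1, base_filters >= 1, n_classes >= 2)
  if (length(input_shape) != 4) stop("input_shape must be (X, Y, Z, channels)",
                                     call. = FALSE)
  sz <- input_shape[1:3]
  pools <- list()
  for (lev in seq_len(depth - 1)) {
    p <- c(2L, 2L, 2L)
    for (ax in 1:2) {
      if (sz[ax] %% 2 != 0)
        stop(sprintf(
          "spatial axis %s (size %d at level %d) is not divisible by 2",
          c("x", "y")[ax], sz[ax], lev), call. = FALSE)
    }
    if (sz[3] %% 2 != 0) p[3] <- 1L
    pools[[lev]] <- p
    sz <- sz %/% p
  }
  rows <- list()
  add <- function(name, kind, kernel, in_ch, out_ch) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, kind = kind, kernel = paste(kernel, collapse = "x"),
      in_channels = in_ch, out_channels = out_ch, stringsAsFactors = FALSE)
  }
  ch <- input_shape[4]
  skip_ch <- integer(depth)
  for (lev in seq_len(depth)) {
    f <- base_filters * 2^(lev - 1)
    add(sprintf("enc%d_conv1", lev), "conv", c(3, 3, 3), ch, f)
    add(sprintf("enc%d_norm1", lev), "instance_norm", NA, f, f)
    add(sprintf("enc%d_conv2", lev), "conv", c(3, 3, 3), f, 2 * f)
    add(sprintf("enc%d_norm2", lev), "instance_norm", NA, 2 * f, 2 * f)
    ch <- 2 * f
    skip_ch[lev] <- ch
    if (lev < depth)
      add(sprintf("enc%d_pool", lev), "max_pool",
          pools[[lev]], ch, ch)
  }
  for (lev in rev(seq_len(depth - 1))) {
    p <- pools[[lev]]
    add(sprintf("dec%d_upconv", lev), "transposed_conv", p, ch, ch)
    add(sprintf("dec%d_concat", lev), "concat", NA, ch + skip_ch[lev],
        ch + skip_ch[lev])
    add(sprintf("dec%d_conv1", lev), "conv", c(3, 3, 3), ch + skip_ch[lev],
        skip_ch[lev])
    add(sprintf("dec%d_norm1", lev), "instance_norm", NA, skip_ch[lev],
        skip_ch[lev])
    add(sprintf("dec%d_conv2", lev), "conv", c(3, 3, 3), skip_ch[lev],
        skip_ch[lev])
    add(sprintf("dec%d_norm2", lev), "instance_norm", NA, skip_ch[lev],
        skip_ch[lev])
    ch <- skip_ch[lev]
  }
  out_ch <- if (n_classes == 2) 1L else n_classes
  add("output_conv", "conv", c(1, 1, 1), ch, out_ch)
  add("output_activation", if (n_classes == 2) "sigmoid" else "softmax", NA,
      out_ch, out_ch)
  structure(list(input_shape = input_shape, depth = depth,
                 base_filters = base_filters, n_classes = n_classes,
                 layers = do.call(rbind, rows)),
            class = "prostasm_network_spec")
}

#' Count trainable parameters of a network specification
#'
#' Convolutions and transposed convolutions contribute
#' `prod(kernel) * in_channels * out_channels + out_channels` (weights +
#' bias); instance normalisation, pooling, concatenation and activations
#' contribute none. Pure metadata: no weights are allocated.
#'
#' @param spec a `prostasm_network_spec`, or any list with a compatible
#'   `layers` data frame.
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  layers <- spec$layers
  if (is.null(layers) || nrow(layers) == 0) return(0)
  total <- 0
  for (r in seq_len(nrow(layers))) {
    kind <- layers$kind[r]
    if (kind %in% c("conv", "transposed_conv")) {
      k <- prod(as.numeric(strsplit(layers$kernel[r], "x")[[1]]))
      total <- total + k * layers$in_channels[r] * layers$out_channels[r] +
        layers$out_channels[r]
    }
  }
  as.integer(total)
}

#' @export
print.prostasm_network_spec <- function(x, ...) {
  cat(sprintf("<VNet-T2 spec> input %s, depth %d, base filters %d, %d classes\n",
              paste(x$input_shape, collapse = "x"), x$depth, x$base_filters,
              x$n_classes))
  print(x$layers, row.names = FALSE)
  cat(sprintf("trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Soft Dice loss between a probability map and a binary target
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` on the foreground
#' probability; the smoothing term `eps` avoids 0/0 on empty masks.
#'
#' @param pred foreground-probability 3D array, or a 4D array whose channels
#'   are `(background, foreground)` (channel 2 is used), or a single-channel
#'   4D array.
#' @param target a `prostasm_mask` or 0/1 array on the same grid.
#' @param epsilon smoothing constant (default `1e-5`).
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, epsilon = 1e-5) {
  p <- prob_foreground(pred)
  t <- if (is_mask(target)) target$data else target
  if (!identical(dim(p), dim(t)))
    stop("prediction and target grids differ: ",
         paste(dim(p), collapse = "x"), " vs ", paste(dim(t), collapse = "x"),
         call. = FALSE)
  1 - (2 * sum(p * t) + epsilon) / (sum(p) + sum(t) + epsilon)
}

# extract the foreground probability channel
prob_foreground <- function(pred) {
  d <- dim(pred)
  if (length(d) == 3) return(pred)
  if (length(d) == 4) {
    ch <- if (d[4] == 1) 1 else 2
    return(array(pred[, , , ch], d[1:3]))
  }
  stop("prediction must be a 3D or 4D probability array", call. = FALSE)
}

#' Inverse-frequency class weights from training masks
#'
#' Weights are inversely proportional to each class's voxel frequency across
#' all masks, normalised to mean 1; the rarer class (the gland) therefore
#' contributes more to a class-weighted loss.
#'
#' @param masks list of `prostasm_mask` (>= 1).
#' @return named numeric `c(background, foreground)` weights.
#' @export
class_weights <- function(masks) {
  if (!is.list(masks) || length(masks) == 0)
    stop("need at least one mask", call. = FALSE)
  fg <- sum(vapply(masks, function(m) sum(m$data), numeric(1)))
  tot <- sum(vapply(masks, function(m) length(m$data), numeric(1)))
  freq <- c(background = (tot - fg) / tot, foreground = fg / tot)
  if (any(freq == 0))
    stop("a class is absent from all masks; cannot weight it", call. = FALSE)
  inv <- 1 / freq
  inv / mean(inv)
}

#' Produce an initial segmentation from a pluggable initializer
#'
#' The initializer abstracts over the source of the rough segmentation that
#' the shape model refines: a trained-network adapter, a precomputed mask, or
#' the phantom corruption surrogate. It is any function `f(vol)` returning
#' either a `prostasm_mask` or a probability array; probabilities are
#' converted to a mask by the per-voxel argmax (foreground probability >=
#' 0.5 for the binary case).
#'
#' @param vol a `prostasm_volume`.
#' @param initializer function of the volume.
#' @return a `prostasm_mask` on `vol`'s grid.
#' @export
initial_segmentation <- function(vol, initializer) {
  stopifnot(is_volume(vol), is.function(initializer))
  res <- tryCatch(initializer(vol), error = function(e)
    stop("initializer failed: ", conditionMessage(e), call. = FALSE))
  if (is_mask(res)) {
    stop_if_grid_mismatch(res, vol, "initializer mask and volume")
    return(res)
  }
  p <- prob_foreground(res)
  if (!identical(dim(p), dim(vol$data)))
    stop("initializer probability grid does not match the volume",
         call. = FALSE)
  as_mask(array(as.integer(p >= 0.5), dim(p)), vol$spacing, vol$origin)
}

#' Surrogate initializer from a reference mask
#'
#' Stands in for a trained network in synthetic experiments: returns the
#' reference mask corrupted with [corrupt_mask()] at the given severity.
#'
#' @param truth reference `prostasm_mask`.
#' @param severity corruption level in `[0, 1]`.
#' @param seed integer seed.
#' @return a function usable as the `initializer` of
#'   [initial_segmentation()].
#' @export
surrogate_initializer <- function(truth, severity = 0.3, seed = 1) {
  force(truth); force(severity); force(seed)
  function(vol) {
    stop_if_grid_mismatch(truth, vol, "surrogate truth mask and volume")
    corrupt_mask(truth, severity, seed)
  }
}
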