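#' Correct a smooth multiplicative bias field
#'
#' MRI volumes are corrupted by a smooth, low-frequency multiplicative
#' intensity non-uniformity (the bias field): `v = u * f + n`, with `u` the
#' uncorrupted image and `f` the field. This routine estimates `log f` inside
#' an automatically derived foreground mask (Otsu threshold) by iteratively
#' reweighted least-squares fitting of a low-order 3D polynomial in the log
#' domain; the robust reweighting (Huber) keeps genuine anatomy edges from
#' being absorbed into the field. The accumulated field is exponentiated,
#' normalised to unit geometric mean inside the mask (so it is strictly
#' positive and mean ~ 1), and divided out everywhere.
#'
#' @param vol a non-negative `prostasm_volume`.
#' @param max_iterations number of reweighting iterations (default 4).
#' @param degree total degree of the 3D polynomial field model (default 3).
#' @return a list with `volume` (corrected) and `bias` (a `prostasm_bias`
#'   with the multiplicative `field` array and `n_iterations`).
#' @export
correct_bias_field <- function(vol, max_iterations = 4, degree = 3) {
  stopifnot(is_volume(vol))
  x <- vol$data
  if (any(x < 0)) stop("bias correction requires non-negative intensities",
                       call. = FALSE)
  if (all(x == 0)) stop("degenerate input: all-zero volume", call. = FALSE)
  thr <- otsu_threshold(x)
  mask <- x > thr
  # the threshold mask can pick up bright patches outside the organ and lose
  # shaded voxels inside it; restrict the fit to the eroded main component
  mm <- as_mask(array(as.integer(mask), dim(x)), vol$spacing, vol$origin)
  mm <- erode_mask(keep_largest_component(mm), min(vol$spacing))
  if (sum(mm$data) >= 50) mask <- mm$data == 1L
  if (sum(mask) < 50) stop("foreground mask too small for bias estimation",
                           call. = FALSE)
  d <- dim(x)
  # normalised coordinates in [-1, 1] for conditioning
  cx <- (seq_len(d[1]) - 1) / max(d[1] - 1, 1) * 2 - 1
  cy <- (seq_len(d[2]) - 1) / max(d[2] - 1, 1) * 2 - 1
  cz <- (seq_len(d[3]) - 1) / max(d[3] - 1, 1) * 2 - 1
  idx <- which(mask, arr.ind = TRUE)
  pows <- expand.grid(i = 0:degree, j = 0:degree, k = 0:degree)
  pows <- pows[rowSums(pows) <= degree, , drop = FALSE]
  basis_at <- function(xs, ys, zs) {
    X <- matrix(0, length(xs), nrow(pows))
    for (t in seq_len(nrow(pows)))
      X[, t] <- xs^pows$i[t] * ys^pows$j[t] * zs^pows$k[t]
    X
  }
  Xm <- basis_at(cx[idx[, 1]], cy[idx[, 2]], cz[idx[, 3]])
  ly <- log(pmax(x[mask], 1e-6))
  w <- rep(1, length(ly))
  beta <- NULL
  for (it in seq_len(max(1L, as.integer(max_iterations)))) {
    fit <- stats::lm.wfit(Xm, ly, w)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    r <- ly - Xm %*% beta
    s <- stats::mad(r)
    if (s <= 0) break
    k <- 1.345 * s
    w <- pmin(1, k / pmax(abs(r), 1e-12))
  }
  # evaluate field on the full grid in chunks to bound memory
  lf <- numeric(length(x))
  grid_idx <- seq_along(x)
  chunk <- 1000000L
  for (start in seq(1L, length(x), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(x))
    i <- (sel - 1L) %% d[1] + 1L
    j <- ((sel - 1L) %/% d[1]) %% d[2] + 1L
    k <- (sel - 1L) %/% (d[1] * d[2]) + 1L
    lf[sel] <- basis_at(cx[i], cy[j], cz[k]) %*% beta
  }
  lf <- lf - mean(lf[as.vector(mask)])
  field <- array(exp(lf), d)
  corrected <- as_volume(x / field, vol$spacing, vol$origin)
  bias <- structure(list(field = field, n_iterations = max_iterations),
                    class = "prostasm_bias")
  list(volume = corrected, bias = bias)
}

#' Learn a standard intensity scale from a training set
#'
#' Implements landmark-based intensity standardisation: a fixed set of
#' percentile landmarks is extracted from the foreground histogram of every
#' training volume (foreground = voxels strictly above the volume median, a
#' rank-based selection that is invariant under monotone intensity maps);
#' each volume's landmarks are affinely mapped so that its lowest/highest
#' landmarks hit `output_range`, and the standard positions are the
#' across-volume means of the mapped landmarks.
#'
#' @param volumes list of `prostasm_volume` objects (>= 2).
#' @param percentiles ordered percentile ranks of the landmarks (default
#'   `c(1, 10, 25, 50, 75, 90, 99)`).
#' @param output_range numeric length-2 standard intensity range (default
#'   `c(0, 4095)`).
#' @param include_mode append the foreground histogram mode as an extra
#'   landmark (off by default: on unimodal foregrounds the mode nearly
#'   coincides with the median and breaks the strictly-increasing landmark
#'   requirement).
#' @return a `prostasm_standard_scale`.
#' @export
learn_standard_scale <- function(volumes,
                                 percentiles = c(1, 10, 25, 50, 75, 90, 99),
                                 output_range = c(0, 4095),
                                 include_mode = FALSE) {
  if (!is.list(volumes) || length(volumes) < 2L)
    stop("need at least 2 training volumes", call. = FALSE)
  if (length(percentiles) < 2L || any(diff(percentiles) <= 0))
    stop("percentiles must be >= 2 strictly increasing ranks", call. = FALSE)
  if (output_range[1] >= output_range[2])
    stop("output_range must be increasing", call. = FALSE)
  mapped <- vapply(volumes, function(v) {
    lm_v <- volume_landmarks(v, percentiles, include_mode)
    rng <- attr(lm_v, "prange")
    (lm_v - rng[1]) / (rng[2] - rng[1]) * diff(output_range) + output_range[1]
  }, numeric(length(percentiles) + include_mode))
  pos <- rowMeans(mapped)
  if (any(diff(pos) <= 0))
    stop("standard positions are not strictly increasing; ",
         "try include_mode = FALSE or fewer landmarks", call. = FALSE)
  structure(list(landmark_percentiles = percentiles,
                 standard_positions = pos,
                 output_range = output_range,
                 include_mode = include_mode),
            class = "prostasm_standard_scale")
}

# Landmark intensities of one volume: foreground percentiles (+ mode).
# The foreground is rank-defined (strictly above the volume median) so that
# it is invariant under any strictly increasing intensity map -- this is
# what makes standardisation idempotent to within interpolation error.
volume_landmarks <- function(vol, percentiles, include_mode = FALSE) {
  stopifnot(is_volume(vol))
  x <- vol$data
  thr <- quantile(x, 0.5, names = FALSE, type = 7)
  fg <- x[x > thr]
  if (length(fg) < 100)
    stop("degenerate histogram: foreground has too few voxels", call. = FALSE)
  if (length(unique(fg)) < length(percentiles) + include_mode + 1L)
    stop("degenerate histogram: fewer distinct intensities than landmarks",
         call. = FALSE)
  lm_v <- as.numeric(quantile(fg, percentiles / 100, names = FALSE, type = 7))
  prange <- c(lm_v[1], lm_v[length(lm_v)])
  if (include_mode) {
    h <- graphics::hist(fg, breaks = 64, plot = FALSE)
    lm_v <- sort(c(lm_v, h$mids[which.max(h$counts)]))
  }
  if (any(diff(lm_v) <= 0))
    stop("degenerate histogram: landmarks are not strictly increasing",
         call. = FALSE)
  attr(lm_v, "prange") <- prange
  lm_v
}

#' Standardise a volume's intensities onto a learned scale
#'
#' Applies the continuous, monotone piecewise-linear map that sends each of
#' the volume's own landmark intensities exactly onto the corresponding
#' standard position; intensities beyond the terminal landmarks are mapped by
#' extending the terminal linear segments.
#'
#' @param vol a `prostasm_volume`.
#' @param scale a `prostasm_standard_scale` from [learn_standard_scale()].
#' @return standardised `prostasm_volume`.
#' @export
standardize_intensity <- function(vol, scale) {
  stopifnot(is_volume(vol), inherits(scale, "prostasm_standard_scale"))
  lm_v <- volume_landmarks(vol, scale$landmark_percentiles,
                           scale$include_mode)
  pos <- scale$standard_positions
  x <- as.numeric(vol$data)
  out <- stats::approx(lm_v, pos, xout = x, rule = 2)$y
  n <- length(lm_v)
  slope_lo <- (pos[2] - pos[1]) / (lm_v[2] - lm_v[1])
  slope_hi <- (pos[n] - pos[n - 1]) / (lm_v[n] - lm_v[n - 1])
  below <- x < lm_v[1]
  above <- x > lm_v[n]
  out[below] <- pos[1] + (x[below] - lm_v[1]) * slope_lo
  out[above] <- pos[n] + (x[above] - lm_v[n]) * slope_hi
  as_volume(array(out, dim(vol$data)), vol$spacing, vol$origin)
}

#' @export
print.prostasm_standard_scale <- function(x, ...) {
  cat("<standard intensity scale>\n  percentiles:",
      paste(x$landmark_percentiles, collapse = ", "),
      if (x$include_mode) "+ mode" else "", "\n  positions:",
      paste(round(x$standard_positions, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Save / load a standard scale as JSON
#' @param scale a `prostasm_standard_scale`.
#' @param path JSON file path.
#' @return `save_standard_scale` returns `path` invisibly;
#'   `load_standard_scale` returns the scale.
#' @export
save_standard_scale <- function(scale, path) {
  stopifnot(inherits(scale, "prostasm_standard_scale"))
  jsonlite::write_json(unclass(scale), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_standard_scale
#' @export
load_standard_scale <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj[c("landmark_percentiles", "standard_positions",
                  "output_range", "include_mode")],
            class = "prostasm_standard_scale")
}
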