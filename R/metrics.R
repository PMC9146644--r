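#' Volumetric segmentation metrics
#'
#' Pairwise comparison of two binary masks on the same grid:
#'
#' * `dsc()` — Dice similarity coefficient `2|A n B| / (|A| + |B|)`
#'   (1 when both masks are empty);
#' * `hd95()` — symmetrised 95th-percentile Hausdorff distance in mm: the
#'   maximum of the two directed 95th percentiles of surface-to-surface
#'   distances (directed variants available via `directed`);
#' * `rvd()` — relative volume difference
#'   `100 * (V_auto - V_ref) / V_ref` in percent; positive values indicate
#'   over-segmentation.
#'
#' Surfaces are 6-connectivity erosion-difference voxels; distances are
#' Euclidean in mm and honour anisotropic spacing.
#'
#' @param a,b,auto,ref `prostasm_mask`s on a common grid.
#' @return scalar metric value.
#' @name metrics
NULL

#' @rdname metrics
#' @export
dsc <- function(a, b) {
  stopifnot(is_mask(a), is_mask(b))
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a$data)
  nb <- sum(b$data)
  if (na + nb == 0) return(1)
  2 * sum(a$data & b$data) / (na + nb)
}

#' @rdname metrics
#' @param directed `"max"` (default, symmetrised), `"ab"` or `"ba"`.
#' @export
hd95 <- function(a, b, directed = c("max", "ab", "ba")) {
  directed <- match.arg(directed)
  stopifnot(is_mask(a), is_mask(b))
  stop_if_grid_mismatch(a, b, "masks")
  if (sum(a$data) == 0 || sum(b$data) == 0)
    stop("hd95 requires two non-empty masks", call. = FALSE)
  pa <- surface_points_mm(a)
  pb <- surface_points_mm(b)
  d_ab <- quantile(RANN::nn2(pb, pa, k = 1)$nn.dists[, 1], 0.95,
                   names = FALSE, type = 7)
  d_ba <- quantile(RANN::nn2(pa, pb, k = 1)$nn.dists[, 1], 0.95,
                   names = FALSE, type = 7)
  switch(directed, ab = d_ab, ba = d_ba, max = max(d_ab, d_ba))
}

#' @rdname metrics
#' @export
rvd <- function(auto, ref) {
  stopifnot(is_mask(auto), is_mask(ref))
  stop_if_grid_mismatch(auto, ref, "masks")
  v_ref <- mask_volume_mm3(ref)
  if (v_ref == 0) stop("rvd requires a non-empty reference mask",
                       call. = FALSE)
  100 * (mask_volume_mm3(auto) - v_ref) / v_ref
}

#' All three metrics as a one-row report
#'
#' @param auto automatic mask.
#' @param ref reference mask on the same grid.
#' @return one-row `data.frame` with `dsc`, `hd95_mm`, `rvd_percent`.
#' @export
evaluate_masks <- function(auto, ref) {
  data.frame(dsc = dsc(auto, ref), hd95_mm = hd95(auto, ref),
             rvd_percent = rvd(auto, ref))
}
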