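#' Build the shape + appearance model archive from a training cohort
#'
#' Full model-construction pass over paired volumes and reference masks:
#' optional preprocessing (bias correction, learned intensity
#' standardisation), isotropic resampling, corresponded-vertex extraction,
#' alignment of every shape to the first, shape PCA at the requested
#' variance, per-vertex appearance profiles with DBSCAN outlier removal,
#' and per-vertex appearance PCA (with a pooled fallback model for vertices
#' left with fewer than 3 inlier profiles).
#'
#' @param volumes list of `prostasm_volume`s.
#' @param masks list of matching `prostasm_mask`s (same length and grids).
#' @param config a [ray_config()].
#' @param variance shape-PCA retained variance (default 0.98).
#' @param iso_target isotropic working resolution in mm (default 0.5).
#' @param ns_model appearance profile half-length (default 2).
#' @param bias_correction,standardize preprocessing toggles (default TRUE).
#' @param dbscan_min_pts DBSCAN `min_pts` for profile filtering (default 8).
#' @param dbscan_eps DBSCAN radius; `NULL` for the k-distance elbow.
#' @return a `prostasm_model_archive`: `shape_model`, `appearance_models`
#'   (length-K list), `pooled_appearance`, `ray_config`, `settings`,
#'   `provenance`.
#' @export
build_models <- function(volumes, masks, config = ray_config(),
                         variance = 0.98, iso_target = 0.5, ns_model = 2,
                         bias_correction = TRUE, standardize = TRUE,
                         dbscan_min_pts = 8, dbscan_eps = NULL) {
  if (length(volumes) != length(masks))
    stop("unpaired inputs: ", length(volumes), " volumes vs ",
         length(masks), " masks", call. = FALSE)
  n <- length(volumes)
  if (n < 3) stop("need at least 3 training pairs for the PCA model",
                  call. = FALSE)
  for (i in seq_len(n)) stop_if_grid_mismatch(volumes[[i]], masks[[i]],
                                              paste0("pair ", i))
  if (bias_correction)
    volumes <- lapply(volumes, function(v) correct_bias_field(v)$volume)
  scale <- NULL
  if (standardize) {
    scale <- learn_standard_scale(volumes)
    volumes <- lapply(volumes, standardize_intensity, scale = scale)
  }
  vols_iso <- lapply(volumes, resample_isotropic, target = iso_target)
  masks_iso <- lapply(masks, resample_isotropic, target = iso_target)
  shapes <- lapply(masks_iso, extract_corresponded_vertices, config = config)
  aligned <- vector("list", n)
  aligned[[1]] <- shapes[[1]]
  for (i in seq.int(2, n))
    aligned[[i]] <- align_shape(shapes[[i]], shapes[[1]])$shape
  smodel <- build_shape_model(aligned, variance = variance)
  # appearance profiles in the original (unaligned) pose of each subject
  K <- smodel$K
  step <- iso_target
  prof_list <- vector("list", n)
  for (i in seq_len(n)) {
    mesh <- mesh_from_vertices(shapes[[i]], alpha = 30)
    normals <- surface_normals(shapes[[i]], mesh, max_dist = 5)
    prof_list[[i]] <- sample_profiles(vols_iso[[i]],
                                      shape_matrix(shapes[[i]]), normals,
                                      ns = ns_model, step = step)
  }
  all_prof <- do.call(rbind, prof_list)
  vertex_of <- rep(seq_len(K), times = n)
  filt <- filter_profiles_dbscan(all_prof, eps = dbscan_eps,
                                 min_pts = dbscan_min_pts)
  inl <- filt$inliers
  pooled <- build_appearance_model(all_prof[inl, , drop = FALSE])
  amodels <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- inl[vertex_of[inl] == k]
    amodels[[k]] <- if (length(rows) >= 3)
      build_appearance_model(all_prof[rows, , drop = FALSE])
    else pooled
  }
  structure(list(
    shape_model = smodel,
    appearance_models = amodels,
    pooled_appearance = pooled,
    ray_config = config,
    settings = list(variance = variance, iso_target = iso_target,
                    ns_model = ns_model, bias_correction = bias_correction,
                    standardize = standardize,
                    dbscan_min_pts = dbscan_min_pts,
                    dbscan_eps = filt$eps,
                    inlier_fraction = length(inl) / nrow(all_prof)),
    standard_scale = scale,
    provenance = list(n_train = n, K = K,
                      package_version = as.character(
                        utils::packageVersion("prostasm")))),
    class = "prostasm_model_archive")
}

#' @export
print.prostasm_model_archive <- function(x, ...) {
  cat(sprintf(paste0("<model archive> K = %d, %d shape mode(s), ",
                     "n_train = %d, inlier fraction %.2f\n"),
              x$provenance$K, length(x$shape_model$lambda),
              x$provenance$n_train, x$settings$inlier_fraction))
  invisible(x)
}

#' Run the full refinement pipeline on one volume
#'
#' Executes the hybrid segmentation chain: preprocessing (mirroring the
#' archive's settings), initial segmentation via the pluggable initializer,
#' mask cleanup (largest component + hole fill, guarding the ray casting
#' against spurious blobs), isotropic resampling, corresponded-vertex
#' extraction, iterative ASM refinement, and mesh-to-mask post-processing
#' back on the native grid. If a reference mask is supplied the result is
#' scored with [evaluate_masks()].
#'
#' @param vol input `prostasm_volume` (native grid).
#' @param init initial segmentation: a `prostasm_mask`, a path to one, or a
#'   function `f(vol)` (see [initial_segmentation()]).
#' @param archive a `prostasm_model_archive` from [build_models()].
#' @param config an [asm_config()] (default the best-performing
#'   configuration).
#' @param reference optional reference `prostasm_mask` for scoring.
#' @param keep_stages return intermediate artifacts (default FALSE).
#' @return list with `mask` (final `prostasm_mask` on the native grid),
#'   `metrics` (one-row data frame or NULL), `log` (ASM iteration log),
#'   `provenance` (config echo, archive K, package version, stage timings),
#'   and optionally `stages`.
#' @export
run_pipeline <- function(vol, init, archive, config = asm_config(),
                         reference = NULL, keep_stages = FALSE) {
  stopifnot(is_volume(vol), inherits(archive, "prostasm_model_archive"))
  t_start <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    now <- proc.time()[["elapsed"]]
    timings[stage] <<- now - t_start - sum(timings)
  }
  init_mask <- if (is_mask(init)) init
    else if (is.character(init)) read_volume(init, mask = TRUE)
    else if (is.function(init)) initial_segmentation(vol, init)
    else stop("init must be a mask, a file path or an initializer function",
              call. = FALSE)
  stop_if_grid_mismatch(init_mask, vol, "initial mask and volume")
  work <- vol
  if (isTRUE(archive$settings$bias_correction))
    work <- correct_bias_field(work)$volume
  if (isTRUE(archive$settings$standardize) &&
      !is.null(archive$standard_scale))
    work <- standardize_intensity(work, archive$standard_scale)
  iso <- archive$settings$iso_target
  work_iso <- resample_isotropic(work, target = iso)
  clean <- fill_holes(keep_largest_component(init_mask))
  init_iso <- resample_isotropic(clean, target = iso)
  init_shape <- extract_corresponded_vertices(init_iso,
                                              config = archive$ray_config)
  if (nrow(shape_matrix(init_shape)) != archive$shape_model$K)
    stop("archive K = ", archive$shape_model$K,
         " is incompatible with the extraction K = ",
         nrow(shape_matrix(init_shape)), call. = FALSE)
  tick("preprocess_and_extract")
  refined <- refine(work_iso, init_shape, archive$shape_model,
                    archive$appearance_models, config)
  tick("refine")
  final <- shape_to_mask(refined, work_iso, vol, alpha = config$alpha)
  tick("postprocess")
  metrics <- if (!is.null(reference)) evaluate_masks(final, reference)
    else NULL
  out <- list(mask = final, metrics = metrics, log = attr(refined, "log"),
              provenance = list(
                config = unclass(config),
                archive_K = archive$shape_model$K,
                package_version = as.character(
                  utils::packageVersion("prostasm")),
                stage_seconds = as.list(timings)))
  if (keep_stages)
    out$stages <- list(initial_mask = init_mask, cleaned_mask = clean,
                       initial_shape = init_shape, refined_shape = refined,
                       working_volume = work_iso)
  out
}

# ---- archive serialisation (portable JSON, text-only) ----------------------

#' Save / load a model archive as JSON
#'
#' The archive (shape model, per-vertex appearance models, ray
#' configuration, settings) is serialised to a single JSON file with full
#' numeric precision, so a rebuilt archive round-trips exactly.
#'
#' @param archive a `prostasm_model_archive`.
#' @param path JSON file path.
#' @return `save_model_archive` returns `path` invisibly;
#'   `load_model_archive` returns the archive.
#' @export
save_model_archive <- function(archive, path) {
  stopifnot(inherits(archive, "prostasm_model_archive"))
  enc_mat <- function(m) list(dim = dim(m), data = as.numeric(m))
  sm <- archive$shape_model
  obj <- list(
    shape_model = list(x_mean = sm$x_mean, Ws = enc_mat(sm$Ws),
                       lambda = sm$lambda,
                       variance_retained = sm$variance_retained,
                       K = sm$K, n_train = sm$n_train,
                       target_variance = sm$target_variance),
    appearance_models = lapply(archive$appearance_models, function(am)
      list(g_mean = am$g_mean, Wg = enc_mat(am$Wg), lambda_g = am$lambda_g,
           n_profiles = am$n_profiles)),
    pooled_appearance = list(g_mean = archive$pooled_appearance$g_mean,
                             Wg = enc_mat(archive$pooled_appearance$Wg),
                             lambda_g = archive$pooled_appearance$lambda_g,
                             n_profiles = archive$pooled_appearance$n_profiles),
    ray_config = unclass(archive$ray_config),
    settings = archive$settings,
    standard_scale = if (!is.null(archive$standard_scale))
      unclass(archive$standard_scale) else NULL,
    provenance = archive$provenance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_model_archive
#' @export
load_model_archive <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path,
                               call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  dec_mat <- function(e) matrix(as.numeric(e$data), nrow = e$dim[1],
                                ncol = e$dim[2])
  sm <- obj$shape_model
  smodel <- structure(list(x_mean = sm$x_mean, Ws = dec_mat(sm$Ws),
                           lambda = as.numeric(sm$lambda),
                           variance_retained = sm$variance_retained,
                           K = sm$K, n_train = sm$n_train,
                           target_variance = sm$target_variance),
                      class = "prostasm_shape_model")
  dec_am <- function(a)
    structure(list(g_mean = as.numeric(a$g_mean), Wg = dec_mat(a$Wg),
                   lambda_g = as.numeric(a$lambda_g),
                   n_profiles = a$n_profiles),
              class = "prostasm_appearance_model")
  amodels <- lapply(obj$appearance_models, dec_am)
  rc <- obj$ray_config
  config <- ray_config(alpha = rc$alpha, n_azimuth = rc$n_azimuth,
                       elevations = as.numeric(rc$elevations),
                       max_surface_points = rc$max_surface_points)
  scale <- if (!is.null(obj$standard_scale))
    structure(obj$standard_scale, class = "prostasm_standard_scale")
    else NULL
  structure(list(shape_model = smodel, appearance_models = amodels,
                 pooled_appearance = dec_am(obj$pooled_appearance),
                 ray_config = config, settings = obj$settings,
                 standard_scale = scale, provenance = obj$provenance),
            class = "prostasm_model_archive")
}
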