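#' ASM search configuration and named presets
#'
#' `asm_config()` collects the parameters of the iterative search: the
#' number of iterations `it`, the search half-length `ns_search` (samples on
#' each side of the current position), the shape-constraint multiplier `m`
#' bounding the PCA coordinates, and the appearance-profile half-length
#' `ns_model`. The four ablation presets are available by name; the default
#' configuration is the best-performing one (it = 2, ns = 8, m = 2).
#'
#' `eigen_scaling` selects how eigenvalues scale the objective and the
#' constraint: `"linear"` divides profile coordinates by `lambda_g` and
#' bounds shape coordinates by `m * lambda_s`; `"sqrt"` uses standard
#' deviations instead (the classical Mahalanobis / 3-sigma form).
#'
#' @param iterations number of search iterations (>= 0).
#' @param ns_search search half-length in samples (>= `ns_model`).
#' @param m shape-constraint multiplier (>= 0).
#' @param ns_model appearance half-length (default 2, i.e. length-5
#'   profiles).
#' @param eigen_scaling `"linear"` (default) or `"sqrt"`.
#' @param alpha alpha radius (mm) for the per-iteration surface
#'   triangulation (default 30).
#' @param step profile/search sample step in mm; `NULL` means one voxel of
#'   the working volume.
#' @return a `prostasm_asm_config`.
#' @export
asm_config <- function(iterations = 2, ns_search = 8, m = 2, ns_model = 2,
                       eigen_scaling = c("linear", "sqrt"), alpha = 30,
                       step = NULL) {
  eigen_scaling <- match.arg(eigen_scaling)
  stopifnot(iterations >= 0, ns_search >= ns_model, m >= 0, ns_model >= 1)
  structure(list(iterations = as.integer(iterations),
                 ns_search = as.integer(ns_search), m = m,
                 ns_model = as.integer(ns_model),
                 eigen_scaling = eigen_scaling, alpha = alpha, step = step),
            class = "prostasm_asm_config")
}

#' @rdname asm_config
#' @param name one of `"ASM-1"`, `"ASM-2"`, `"ASM-3"`, `"ASM-4"`.
#' @export
asm_preset <- function(name) {
  presets <- list(`ASM-1` = c(1, 8, 3), `ASM-2` = c(2, 8, 1),
                  `ASM-3` = c(2, 8, 2), `ASM-4` = c(2, 8, 3))
  if (!name %in% names(presets))
    stop("unknown preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")", call. = FALSE)
  p <- presets[[name]]
  asm_config(iterations = p[1], ns_search = p[2], m = p[3])
}

eigen_denominator <- function(lambda, scaling) {
  if (scaling == "sqrt") sqrt(lambda) else lambda
}

#' Appearance objective for a candidate profile
#'
#' The quadratic cost `f = sum((bc_i / lambda_g_i)^2)` with
#' `bc = Wg' (g - g_mean)`: zero when the candidate profile projects onto
#' the mean, growing with eigenvalue-scaled deviation along each appearance
#' mode, and invariant to deviations orthogonal to the model's span.
#' Zero-eigenvalue modes are excluded with a warning.
#'
#' @param g_sub candidate profile (length must match the model).
#' @param model a `prostasm_appearance_model`.
#' @param eigen_scaling `"linear"` (default, divide by eigenvalue) or
#'   `"sqrt"` (divide by standard deviation).
#' @return non-negative scalar.
#' @export
profile_cost <- function(g_sub, model, eigen_scaling = "linear") {
  if (length(g_sub) != length(model$g_mean))
    stop("profile length ", length(g_sub), " does not match model length ",
         length(model$g_mean), call. = FALSE)
  if (length(model$lambda_g) == 0) return(0)
  ok <- model$lambda_g > 1e-12
  if (!all(ok)) warning("excluding ", sum(!ok),
                        " zero-eigenvalue appearance mode(s)")
  bc <- crossprod(model$Wg[, ok, drop = FALSE], g_sub - model$g_mean)
  den <- eigen_denominator(model$lambda_g[ok], eigen_scaling)
  sum((bc / den)^2)
}

# vectorised cost of many candidate profiles (rows) under one model
profile_cost_rows <- function(G, model, eigen_scaling = "linear") {
  if (length(model$lambda_g) == 0) return(rep(0, nrow(G)))
  ok <- model$lambda_g > 1e-12
  Wg <- model$Wg[, ok, drop = FALSE]
  den <- eigen_denominator(model$lambda_g[ok], eigen_scaling)
  B <- sweep(G, 2, model$g_mean) %*% Wg
  rowSums(sweep(B, 2, den, `/`)^2)
}

#' Best boundary movement along a normal
#'
#' Samples an extended profile of length `2 * (ns_search + ns_model) + 1`
#' along the normal, evaluates the appearance objective on every centred
#' sub-profile of length `2 * ns_model + 1` (candidate positions
#' `ind = 1 .. 2 * ns_search + 1`), and returns the signed sample offset
#' `movement = (ind_min - 1) - ns_search`, in `[-ns_search, +ns_search]`.
#' Ties are resolved toward the smallest `|movement|`.
#'
#' @param vol a `prostasm_volume`.
#' @param point,normal surface point and outward unit normal.
#' @param model a `prostasm_appearance_model`.
#' @param ns_search search half-length (>= model half-length).
#' @param eigen_scaling see [profile_cost()].
#' @param step sample step in mm.
#' @return integer movement in samples.
#' @export
best_movement <- function(vol, point, normal, model, ns_search = 8,
                          eigen_scaling = "linear",
                          step = min(vol$spacing)) {
  ns_model <- (length(model$g_mean) - 1) %/% 2
  ext <- sample_profile(vol, point, normal, ns = ns_search + ns_model, step)
  movement_from_profile(ext, model, ns_search, ns_model, eigen_scaling)
}

movement_from_profile <- function(ext, model, ns_search, ns_model,
                                  eigen_scaling) {
  n_cand <- 2 * ns_search + 1
  m <- 2 * ns_model + 1
  G <- t(vapply(seq_len(n_cand), function(ind) ext[ind:(ind + m - 1)],
                numeric(m)))
  f <- profile_cost_rows(G, model, eigen_scaling)
  mv <- (seq_len(n_cand) - 1) - ns_search
  best <- which(f <= min(f) + 1e-12)
  mv[best[which.min(abs(mv[best]))]]
}

#' Constrain a shape to the plausible region of the model
#'
#' Projects the shape onto the PCA basis (`b = Ws' (x - x_mean)`), clamps
#' each coordinate into `[-m * lambda_i, +m * lambda_i]` (or the
#' square-root form), discards the residual orthogonal to the span, and
#' reconstructs `x = x_mean + Ws b`. Idempotent; `m = 0` returns the mean
#' shape.
#'
#' @param x_search a `prostasm_shape` aligned to the model frame.
#' @param model a `prostasm_shape_model`.
#' @param m constraint multiplier (>= 0).
#' @param eigen_scaling `"linear"` (default) or `"sqrt"`.
#' @return `list(shape, b, clamped)`; `clamped` flags per mode.
#' @export
constrain_shape <- function(x_search, model, m, eigen_scaling = "linear") {
  x <- flatten_shape(x_search)
  if (length(x) != length(model$x_mean))
    stop("shape has K = ", length(x) / 3, " but the model expects K = ",
         model$K, call. = FALSE)
  t_modes <- length(model$lambda)
  if (t_modes == 0) {
    return(list(shape = as_shape(unflatten_shape(model$x_mean),
                                 attr(x_search, "ray_config")),
                b = numeric(0), clamped = logical(0)))
  }
  b <- as.numeric(crossprod(model$Ws, x - model$x_mean))
  bmax <- m * eigen_denominator(model$lambda, eigen_scaling)
  clamped <- abs(b) > bmax
  b_cl <- pmin(pmax(b, -bmax), bmax)
  x_out <- model$x_mean + as.numeric(model$Ws %*% b_cl)
  list(shape = as_shape(unflatten_shape(x_out), attr(x_search, "ray_config")),
       b = b_cl, clamped = clamped)
}

#' Refine a corresponded shape against an image with the ASM
#'
#' Runs the iterative active shape model search: at each iteration the
#' current shape is (1) meshed and its outward normals recomputed, (2) every
#' vertex is moved along its normal to the position minimising the
#' appearance objective within the search range, (3) the moved shape is
#' aligned to the model frame, (4) its PCA coordinates are clamped to the
#' plausible region (`|b_i| <= m * lambda_i`), and (5) the alignment is
#' inverted to restore the original pose. With `iterations = 0` the input is
#' returned unchanged.
#'
#' @param vol a `prostasm_volume` on an isotropic grid.
#' @param init initial `prostasm_shape` (e.g. from
#'   [extract_corresponded_vertices()] on the initializer's mask).
#' @param smodel a `prostasm_shape_model`.
#' @param amodels per-vertex list of `prostasm_appearance_model`s (length K)
#'   or a single pooled model.
#' @param config an [asm_config()].
#' @return refined `prostasm_shape`; attributes `b` (final constrained
#'   coordinates) and `log` (per-iteration mean absolute movement and clamp
#'   counts).
#' @export
refine <- function(vol, init, smodel, amodels, config = asm_config()) {
  stopifnot(is_volume(vol), inherits(smodel, "prostasm_shape_model"))
  current <- init
  K <- nrow(shape_matrix(init))
  if (K != smodel$K)
    stop("initial shape K = ", K, " does not match the model K = ",
         smodel$K, call. = FALSE)
  per_vertex <- is.list(amodels) &&
    !inherits(amodels, "prostasm_appearance_model")
  if (per_vertex && length(amodels) != K)
    stop("need one appearance model per vertex (", K, ")", call. = FALSE)
  step <- if (is.null(config$step)) min(vol$spacing) else config$step
  log_rows <- list()
  b_final <- NULL
  for (it in seq_len(config$iterations)) {
    res <- tryCatch({
      mesh <- mesh_from_vertices(current, alpha = config$alpha)
      normals <- surface_normals(current, mesh, max_dist = 5)
      pts <- shape_matrix(current)
      ext <- sample_profiles(vol, pts, normals,
                             ns = config$ns_search + config$ns_model, step)
      moves <- vapply(seq_len(K), function(k) {
        mdl <- if (per_vertex) amodels[[k]] else amodels
        movement_from_profile(ext[k, ], mdl, config$ns_search,
                              config$ns_model, config$eigen_scaling)
      }, numeric(1))
      moved <- as_shape(pts + normals * (moves * step),
                        attr(current, "ray_config"))
      al <- align_shape(moved, mean_shape(smodel))
      con <- constrain_shape(al$shape, smodel, config$m,
                             config$eigen_scaling)
      list(shape = invert_alignment(con$shape, al$transform),
           moves = moves, clamped = con$clamped, b = con$b)
    }, error = function(e)
      stop("ASM iteration ", it, " failed: ", conditionMessage(e),
           call. = FALSE))
    current <- res$shape
    b_final <- res$b
    log_rows[[it]] <- data.frame(iteration = it,
                                 mean_abs_movement = mean(abs(res$moves)),
                                 n_clamped = sum(res$clamped))
  }
  attr(current, "b") <- b_final
  attr(current, "log") <- if (length(log_rows)) do.call(rbind, log_rows)
    else data.frame(iteration = integer(0), mean_abs_movement = numeric(0),
                    n_clamped = integer(0))
  current
}
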