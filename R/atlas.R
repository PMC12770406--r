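#' Laplacian sharpening of an intensity volume
#'
#' `out = image - alpha * L(image)` with `L` the 6-neighbour discrete
#' Laplacian (replicated edges), clamped to the input intensity range.
#' Used after each groupwise averaging step to counteract the blurring
#' introduced by averaging.
#'
#' @param image An [image_volume()].
#' @param alpha Sharpening amount, >= 0 (0 is the identity).
#' @return The sharpened [image_volume()].
#' @export
laplacian_sharpen <- function(image, alpha) {
  stopifnot(inherits(image, "image_volume"))
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (alpha == 0) return(image)
  x <- image$voxels
  lap <- -6 * x
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      lap <- lap + shift_replicate(x, axis, dir)
    }
  }
  out <- x - alpha * lap
  rng <- range(x)
  out <- pmin(pmax(out, rng[1]), rng[2])
  image_volume(array(out, dim(x)), affine = image$affine)
}

# One-voxel shift with replicated (clamped) edges.
shift_replicate <- function(a, axis, dir) {
  dims <- dim(a)
  n <- dims[axis]
  src <- pmin(pmax(seq_len(n) + dir, 1L), n)
  idx <- list(quote(expr =), quote(expr =), quote(expr =))
  idx[[axis]] <- src
  do.call(`[`, c(list(a), idx))
}

# World transform matrix from registration parameters. Parameters act
# about `centre` (fixed-image world centre): p' = A (p - c) + c + t.
transform_matrix <- function(par, model, centre) {
  t_ <- par[1:3]
  A <- if (model == "rigid") {
    euler_rotation(par[4], par[5], par[6])
  } else {
    diag(3) + matrix(par[4:12], 3, 3)
  }
  Tw <- diag(4)
  Tw[1:3, 1:3] <- A
  Tw[1:3, 4] <- centre + t_ - A %*% centre
  Tw
}

euler_rotation <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

sample_moving <- function(moving, fixed, Tw) {
  M <- solve(moving$affine) %*% Tw %*% fixed$affine
  resample_affine_cpp(moving$voxels, dim(moving$voxels), M,
                      dim(fixed$voxels), 1L, NA_real_)
}

ncc_similarity <- function(fixed_vals, moved_vals) {
  ok <- !is.na(moved_vals)
  if (sum(ok) < 0.2 * length(fixed_vals)) return(-1)
  f <- fixed_vals[ok]
  m <- moved_vals[ok]
  if (stats::sd(f) == 0 || stats::sd(m) == 0) return(0)
  stats::cor(f, m)
}

#' Register one image to a fixed reference
#'
#' Estimates a rigid (6-parameter) or affine (12-parameter) world
#' transform maximising normalised cross-correlation, by multi-resolution
#' Nelder-Mead optimisation over a trilinear resampler. Registering an
#' image to itself returns a near-identity transform.
#'
#' @param fixed,moving [image_volume()] objects with overlapping fields of
#'   view.
#' @param model `"rigid"` or `"affine"`.
#' @param init Optional initial `spatial_transform` (e.g. a rigid result
#'   used to initialise an affine refinement).
#' @param maxit Optimisation iteration budget (per resolution level).
#' @return An object of class `spatial_transform`: the 4x4 world matrix
#'   mapping fixed-space points to moving-space points, the model, the
#'   final similarity and a convergence flag.
#' @export
register_pair <- function(fixed, moving, model = c("rigid", "affine"),
                          init = NULL, maxit = 300) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"))
  model <- match.arg(model)
  centre <- as.numeric(fixed$affine %*% c((dim(fixed$voxels) - 1) / 2, 1))[1:3]

  n_par <- if (model == "rigid") 6L else 12L
  par0 <- numeric(n_par)
  if (!is.null(init)) {
    A <- init$matrix[1:3, 1:3]
    t_ <- init$matrix[1:3, 4] - centre + A %*% centre
    if (model == "affine") {
      par0 <- c(t_, as.numeric(A - diag(3)))
    } else {
      par0[1:3] <- t_
      # extract XYZ Euler angles from the rotation part
      par0[5] <- asin(pmin(pmax(-A[3, 1], -1), 1))
      par0[4] <- atan2(A[3, 2], A[3, 3])
      par0[6] <- atan2(A[2, 1], A[1, 1])
    }
  }
  parscale <- if (model == "rigid") {
    c(1, 1, 1, 0.02, 0.02, 0.02)
  } else {
    c(1, 1, 1, rep(0.02, 9))
  }

  # coarse level: robust simplex search; fine level: quasi-Newton polish
  levels <- list(
    list(fixed = resample_image(fixed, 2 * max(fixed$spacing)),
         moving = resample_image(moving, 2 * max(moving$spacing)),
         maxit = maxit, method = "Nelder-Mead"),
    list(fixed = fixed, moving = moving, maxit = ceiling(maxit / 3),
         method = "BFGS")
  )
  par <- par0
  value <- NA_real_
  converged <- TRUE
  for (lev in levels) {
    fvals <- as.numeric(lev$fixed$voxels)
    objective <- function(p) {
      Tw <- transform_matrix(p, model, centre)
      -ncc_similarity(fvals, sample_moving(lev$moving, lev$fixed, Tw))
    }
    fit <- stats::optim(par, objective, method = lev$method,
                        control = list(maxit = lev$maxit, parscale = parscale,
                                       reltol = 1e-8))
    par <- fit$par
    value <- -fit$value
  }
  if (value < 0.1) {
    warning(sprintf("registration may have failed (final similarity %.3f)",
                    value))
    converged <- FALSE
  }
  structure(
    list(matrix = transform_matrix(par, model, centre), model = model,
         similarity = value, converged = converged, centre = centre,
         par = par),
    class = "spatial_transform"
  )
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat("<spatial_transform> ", x$model, ", similarity ",
      round(x$similarity, 4), if (!x$converged) " (not converged)", "\n",
      sep = "")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Resample a moving image into a fixed image's space
#'
#' @param moving The [image_volume()] to warp.
#' @param transform A `spatial_transform` from [register_pair()] (or any
#'   list with a 4x4 `matrix` mapping fixed-world to moving-world).
#' @param fixed The [image_volume()] (or `label_volume`) defining the
#'   target grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return An [image_volume()] on the fixed grid.
#' @export
apply_transform <- function(moving, transform, fixed,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  M <- solve(moving$affine) %*% transform$matrix %*% fixed$affine
  out <- resample_affine_cpp(moving$voxels, dim(moving$voxels), M,
                             dim(fixed$voxels),
                             if (interpolation == "linear") 1L else 0L, 0)
  image_volume(array(out, dim(fixed$voxels)), affine = fixed$affine)
}

#' Atlas construction configuration
#'
#' @param iterations Number of register-average-sharpen iterations.
#' @param target_spacing Isotropic template spacing in mm.
#' @param sharpen_alpha Laplacian sharpening amount applied after each
#'   averaging step.
#' @param nonrigid Optional pluggable non-rigid refinement: a
#'   `function(template, warped_image)` returning an [image_volume()] on
#'   the template grid; `NULL` disables the non-rigid stage.
#' @param maxit Optimiser budget passed to [register_pair()].
#' @return An object of class `atlas_config`.
#' @export
atlas_config <- function(iterations = 5L, target_spacing = 0.8,
                         sharpen_alpha = 0.5, nonrigid = NULL, maxit = 300) {
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  if (sharpen_alpha < 0) stop("sharpen_alpha must be >= 0", call. = FALSE)
  structure(
    list(iterations = as.integer(iterations), target_spacing = target_spacing,
         sharpen_alpha = sharpen_alpha, nonrigid = nonrigid, maxit = maxit),
    class = "atlas_config"
  )
}

#' Build a population-averaged atlas
#'
#' Groupwise template construction: the initial reference is the first
#' image resampled to the target spacing; each iteration registers every
#' image to the current template (rigid, then affine initialised from the
#' rigid result, then the optional pluggable non-rigid stage), averages
#' the warped images voxelwise and applies Laplacian sharpening.
#' Deterministic given its inputs.
#'
#' @param images List of [image_volume()] objects (>= 2).
#' @param cfg An [atlas_config()].
#' @return The atlas as an [image_volume()].
#' @export
build_atlas <- function(images, cfg = atlas_config()) {
  stopifnot(inherits(cfg, "atlas_config"))
  if (length(images) < 2) stop("need >= 2 images to build an atlas", call. = FALSE)
  for (im in images) stopifnot(inherits(im, "image_volume"))

  template <- resample_image(images[[1]], cfg$target_spacing)
  for (it in seq_len(cfg$iterations)) {
    warped <- list()
    for (i in seq_along(images)) {
      w <- tryCatch({
        t_rigid <- register_pair(template, images[[i]], "rigid",
                                 maxit = cfg$maxit)
        t_aff <- register_pair(template, images[[i]], "affine",
                               init = t_rigid, maxit = cfg$maxit)
        out <- apply_transform(images[[i]], t_aff, template)
        if (!is.null(cfg$nonrigid)) out <- cfg$nonrigid(template, out)
        out
      }, error = function(e) {
        warning(sprintf("iteration %d: skipping image %d (%s)", it, i,
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(w)) warped[[length(warped) + 1L]] <- w
    }
    if (length(warped) < 2) {
      stop("fewer than 2 images survived registration", call. = FALSE)
    }
    avg <- Reduce(`+`, lapply(warped, function(w) w$voxels)) / length(warped)
    template <- laplacian_sharpen(
      image_volume(avg, affine = template$affine), cfg$sharpen_alpha
    )
  }
  template
}
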