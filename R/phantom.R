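#' Parametric cervix phantom specification
#'
#' Defines a synthetic cervix with analytically known geometry: a canal
#' modelled as a tube of radius `canal_radius` around the two-segment
#' centreline inlet -> mid -> outlet (flat-cut at the inlet and outlet
#' planes so the canal has clean open ends touching background), wrapped in
#' concentric inner-stroma and outer-stroma shells, with optional cyst
#' spheres inside the canal and an optional bladder sphere beyond the inlet.
#'
#' The centreline is exactly two straight segments, so the two-line cervical
#' length definition (inlet to midpoint to outlet) is the true arc length;
#' curvature is expressed through the inlet-mid-outlet angle.
#'
#' @param inlet_point,mid_point,outlet_point Numeric length-3 world
#'   coordinates in mm of the canal centreline.
#' @param canal_radius Canal tube radius in mm.
#' @param inner_thickness,outer_thickness Shell thicknesses in mm.
#' @param cysts List of `list(centre = c(x,y,z), radius = r)` spheres; each
#'   must lie entirely inside the canal tube (flush against an end cap is
#'   allowed).
#' @param include_bladder Add a bladder sphere beyond the inlet opening.
#' @param bladder_radius Bladder sphere radius in mm.
#' @param grid_size Voxels per axis (scalar or length 3). If `NULL`, sized
#'   automatically to fit the geometry with a margin.
#' @param spacing Isotropic voxel spacing in mm.
#' @param supersampling Samples per voxel axis for majority-vote
#'   rasterization (default 3, i.e. 27 samples per voxel).
#' @param seed Integer seed carried by the spec (used by downstream
#'   stochastic consumers; rasterization itself is deterministic).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(inlet_point, mid_point, outlet_point,
                         canal_radius = 3, inner_thickness = 3,
                         outer_thickness = 4, cysts = list(),
                         include_bladder = FALSE, bladder_radius = 10,
                         grid_size = NULL, spacing = 0.8,
                         supersampling = 3L, seed = 1L) {
  inlet_point <- as.numeric(inlet_point)
  mid_point <- as.numeric(mid_point)
  outlet_point <- as.numeric(outlet_point)
  stopifnot(length(inlet_point) == 3, length(mid_point) == 3,
            length(outlet_point) == 3)
  if (canal_radius <= 0 || inner_thickness <= 0 || outer_thickness <= 0) {
    stop("radii and thicknesses must be positive", call. = FALSE)
  }
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  if (supersampling < 1) stop("supersampling must be >= 1", call. = FALSE)
  l1 <- sqrt(sum((inlet_point - mid_point)^2))
  l2 <- sqrt(sum((outlet_point - mid_point)^2))
  if (l1 < canal_radius || l2 < canal_radius) {
    stop("centreline segments must be longer than the canal radius",
         call. = FALSE)
  }

  u1 <- (inlet_point - mid_point) / l1   # unit vector out of the inlet end
  u2 <- (outlet_point - mid_point) / l2
  for (cy in cysts) {
    centre <- as.numeric(cy$centre)
    r <- as.numeric(cy$radius)
    if (r <= 0) stop("cyst radius must be positive", call. = FALSE)
    d_axis <- min(point_segment_distance(centre, inlet_point, mid_point),
                  point_segment_distance(centre, mid_point, outlet_point))
    tol <- 1e-6
    if (d_axis + r > canal_radius + tol ||
        sum((centre - inlet_point) * u1) + r > tol ||
        sum((centre - outlet_point) * u2) + r > tol) {
      stop("cyst sphere lies outside the canal tube", call. = FALSE)
    }
  }

  bladder_centre <- NULL
  if (isTRUE(include_bladder)) {
    if (bladder_radius <= 0) stop("bladder_radius must be positive", call. = FALSE)
    # fluid-filled sphere beyond the inlet opening, clear of the outer shell
    bladder_centre <- inlet_point + u1 * (bladder_radius + 3)
  }

  r_outer <- canal_radius + inner_thickness + outer_thickness
  pts <- rbind(inlet_point, mid_point, outlet_point)
  lo <- apply(pts, 2, min) - r_outer
  hi <- apply(pts, 2, max) + r_outer
  if (!is.null(bladder_centre)) {
    lo <- pmin(lo, bladder_centre - bladder_radius)
    hi <- pmax(hi, bladder_centre + bladder_radius)
  }
  margin <- 2 * spacing
  lo <- lo - margin
  hi <- hi + margin
  if (is.null(grid_size)) {
    dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
    origin <- lo
  } else {
    dims <- rep_len(as.integer(grid_size), 3L)
    centre <- (lo + hi) / 2
    origin <- centre - (dims - 1) / 2 * spacing
    if (any((dims - 1) * spacing < hi - lo)) {
      stop("geometry (with margin) exceeds the requested grid", call. = FALSE)
    }
  }
  affine <- diag(c(rep(spacing, 3), 1))
  affine[1:3, 4] <- origin

  structure(
    list(inlet_point = inlet_point, mid_point = mid_point,
         outlet_point = outlet_point, canal_radius = canal_radius,
         inner_thickness = inner_thickness, outer_thickness = outer_thickness,
         cysts = cysts, include_bladder = isTRUE(include_bladder),
         bladder_centre = bladder_centre, bladder_radius = bladder_radius,
         grid_size = dims, spacing = spacing, affine = affine,
         supersampling = as.integer(supersampling), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

#' Generate a phantom label volume with analytic ground truth
#'
#' Rasterizes the phantom by supersampled majority vote (ties broken by
#' label priority cyst > canal > inner > outer) and returns it together
#' with a `phantom_truth` record: the exact two-line cervical length,
#' inlet/outlet diameters (both `2 * canal_radius`), and per-label volumes.
#' Volumes use closed forms when the centreline is straight; for bent
#' centrelines (where the elbow region has no simple closed form) they are
#' computed by fine geometric quadrature of the continuous implicit solid,
#' independent of the rasterization grid.
#'
#' @param spec A [phantom_spec()].
#' @param truth_volumes `"auto"` (closed form when straight, else
#'   quadrature), `"quadrature"`, or `"none"` (skip volume computation;
#'   length and diameters are always exact and free).
#' @param quad_step Quadrature sampling step in mm.
#' @return A list with elements `labels` ([label_volume()]) and `truth`
#'   (class `phantom_truth`).
#' @export
generate_phantom <- function(spec, truth_volumes = c("auto", "quadrature", "none"),
                             quad_step = 0.15) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth_volumes <- match.arg(truth_volumes)

  n_cyst <- length(spec$cysts)
  cyst_centres <- matrix(0, 3, max(1L, n_cyst))
  cyst_radii <- numeric(n_cyst)
  if (n_cyst > 0) {
    for (i in seq_len(n_cyst)) {
      cyst_centres[, i] <- as.numeric(spec$cysts[[i]]$centre)
      cyst_radii[i] <- as.numeric(spec$cysts[[i]]$radius)
    }
  }
  bl_centre <- if (spec$include_bladder) spec$bladder_centre else c(0, 0, 0)
  bl_radius <- if (spec$include_bladder) spec$bladder_radius else -1

  vox <- phantom_rasterize_cpp(
    spec$grid_size, spec$affine, spec$supersampling,
    spec$inlet_point, spec$mid_point, spec$outlet_point,
    spec$canal_radius, spec$inner_thickness, spec$outer_thickness,
    cyst_centres, cyst_radii, bl_centre, bl_radius
  )
  labels <- label_volume(array(vox, spec$grid_size), affine = spec$affine)
  truth <- phantom_truth(spec, truth_volumes, quad_step,
                         cyst_centres, cyst_radii, bl_centre, bl_radius)
  list(labels = labels, truth = truth)
}

phantom_truth <- function(spec, truth_volumes, quad_step,
                          cyst_centres, cyst_radii, bl_centre, bl_radius) {
  l1 <- sqrt(sum((spec$inlet_point - spec$mid_point)^2))
  l2 <- sqrt(sum((spec$outlet_point - spec$mid_point)^2))
  length_mm <- l1 + l2
  u1 <- (spec$inlet_point - spec$mid_point) / l1
  u2 <- (spec$outlet_point - spec$mid_point) / l2
  collinear <- sum(u1 * u2) < -1 + 1e-9

  volumes <- NULL
  if (truth_volumes != "none") {
    r <- spec$canal_radius
    ri <- r + spec$inner_thickness
    ro <- ri + spec$outer_thickness
    cyst_vol <- sum(4 / 3 * pi * cyst_radii^3)
    if (truth_volumes == "auto" && collinear) {
      L <- length_mm
      volumes <- c(canal = pi * r^2 * L - cyst_vol,
                   inner_stroma = pi * (ri^2 - r^2) * L,
                   outer_stroma = pi * (ro^2 - ri^2) * L,
                   cyst = cyst_vol,
                   bladder = if (spec$include_bladder) 4 / 3 * pi * spec$bladder_radius^3 else 0)
    } else {
      pts <- rbind(spec$inlet_point, spec$mid_point, spec$outlet_point)
      lo <- apply(pts, 2, min) - ro - quad_step
      hi <- apply(pts, 2, max) + ro + quad_step
      if (spec$include_bladder) {
        lo <- pmin(lo, spec$bladder_centre - spec$bladder_radius - quad_step)
        hi <- pmax(hi, spec$bladder_centre + spec$bladder_radius + quad_step)
      }
      v <- phantom_sample_volumes_cpp(
        lo, hi, quad_step,
        spec$inlet_point, spec$mid_point, spec$outlet_point,
        spec$canal_radius, spec$inner_thickness, spec$outer_thickness,
        cyst_centres, cyst_radii, bl_centre, bl_radius
      )
      volumes <- c(canal = v[1], inner_stroma = v[2], outer_stroma = v[3],
                   cyst = v[4], bladder = v[5])
    }
  }

  structure(
    list(length_mm = length_mm,
         inlet_diameter_mm = 2 * spec$canal_radius,
         outlet_diameter_mm = 2 * spec$canal_radius,
         volumes_mm3 = volumes,
         collinear = collinear),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> length ", round(x$length_mm, 3), " mm, diameters ",
      round(x$inlet_diameter_mm, 3), " mm\n", sep = "")
  if (!is.null(x$volumes_mm3)) {
    v <- x$volumes_mm3
    cat("  volumes (mm^3): ",
        paste(names(v), round(v, 1), sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Intensity model for T2w-like phantom rendering
#'
#' Per-label mean intensities mirror the T2w appearance of the cervix: the
#' canal is a regional mixture of high and low signal (mucus), the inner
#' stroma is darkest, the outer stroma intermediate and slightly darker
#' than surrounding tissue, cysts are the brightest focal regions.
#'
#' @param means Named per-label mean intensities (names as in
#'   [cervix_labels]).
#' @param canal_mix Amplitude of the smooth zero-mean regional modulation
#'   applied inside the canal (0 disables it, making the noise-free render
#'   exactly piecewise constant).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param bias_amplitude Amplitude of the multiplicative smooth bias field
#'   (0 disables it).
#' @param bias_scale Smoothness scale of the bias field in mm.
#' @param seed Integer seed; rendering is deterministic given the seed.
#' @return An object of class `intensity_model`.
#' @export
intensity_model <- function(means = c(background = 0.55, canal = 0.75,
                                      inner_stroma = 0.20, outer_stroma = 0.45,
                                      cyst = 0.95, bladder = 0.90),
                            canal_mix = 0.15, noise_sd = 0.02,
                            bias_amplitude = 0.1, bias_scale = 40,
                            seed = 1L) {
  stopifnot(all(names(cervix_labels) %in% names(means)))
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (bias_amplitude < 0) stop("bias_amplitude must be non-negative", call. = FALSE)
  if (means[["inner_stroma"]] >= min(means[["canal"]], means[["outer_stroma"]],
                                     means[["cyst"]])) {
    stop("inner stroma must be the darkest cervical layer", call. = FALSE)
  }
  if (means[["cyst"]] <= means[["canal"]]) {
    stop("cysts must be brighter than the canal", call. = FALSE)
  }
  structure(
    list(means = means[names(cervix_labels)], canal_mix = canal_mix,
         noise_sd = noise_sd, bias_amplitude = bias_amplitude,
         bias_scale = bias_scale, seed = as.integer(seed)),
    class = "intensity_model"
  )
}

#' Render a T2w-like intensity image from a label volume
#'
#' Assigns per-label mean intensities, adds a smooth zero-mean regional
#' modulation inside the canal (mixed high/low mucus signal), applies a
#' smooth multiplicative bias field, and adds Gaussian noise. Deterministic
#' given `model$seed`; the caller's RNG state is left untouched.
#'
#' @param labels A [label_volume()].
#' @param model An [intensity_model()].
#' @return An [image_volume()] on the same grid.
#' @export
render_intensity <- function(labels, model) {
  stopifnot(inherits(labels, "label_volume"), inherits(model, "intensity_model"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(model$seed)

  dims <- dim(labels$voxels)
  img <- array(model$means[labels$voxels + 1L], dims)

  # normalized world coordinates of all voxels, for the smooth fields
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1,
                               y = seq_len(dims[2]) - 1,
                               z = seq_len(dims[3]) - 1))
  world <- voxel_to_world(labels, idx)
  ctr <- colMeans(world)
  w <- sweep(world, 2, ctr)

  if (model$canal_mix > 0) {
    in_canal <- labels$voxels == cervix_labels[["canal"]]
    if (any(in_canal)) {
      phase <- runif(3, 0, 2 * pi)
      lambda <- 8 # mm; regional mucus variation scale
      field <- sin(2 * pi * w[, 1] / lambda + phase[1]) +
        sin(2 * pi * w[, 2] / lambda + phase[2]) +
        sin(2 * pi * w[, 3] / lambda + phase[3])
      field <- array(field / 3, dims)
      img[in_canal] <- img[in_canal] + model$canal_mix * field[in_canal]
    }
  }

  if (model$bias_amplitude > 0) {
    s <- w / model$bias_scale
    coef <- rnorm(9, sd = model$bias_amplitude)
    q <- coef[1] * s[, 1] + coef[2] * s[, 2] + coef[3] * s[, 3] +
      coef[4] * s[, 1]^2 + coef[5] * s[, 2]^2 + coef[6] * s[, 3]^2 +
      coef[7] * s[, 1] * s[, 2] + coef[8] * s[, 2] * s[, 3] +
      coef[9] * s[, 1] * s[, 3]
    img <- img * array(exp(q - mean(q)), dims)
  }

  if (model$noise_sd > 0) {
    img <- img + array(rnorm(length(img), sd = model$noise_sd), dims)
  }

  image_volume(img, affine = labels$affine)
}

#' Generate a randomized suite of phantom specifications
#'
#' Draws `n` two-segment cervix phantoms with total centreline length,
#' canal radius and bend angle sampled uniformly from the given ranges,
#' random arm split (0.4-0.6 of the total length), random 3D orientation
#' and random shell thicknesses. Used for seeded parameter-recovery
#' evaluation of the biometry pipeline against analytic ground truth.
#'
#' @param n Number of phantoms.
#' @param seed Integer seed.
#' @param length_range Total two-line length range in mm.
#' @param radius_range Canal radius range in mm.
#' @param bend_range Inlet-mid-outlet angle range in degrees (180 =
#'   straight).
#' @param inner_range,outer_range Shell thickness ranges in mm.
#' @param spacing Isotropic voxel spacing in mm.
#' @param supersampling Rasterization supersampling per axis.
#' @param cyst_prob Probability that a phantom carries one or two cyst
#'   spheres inside the canal (0 disables cysts).
#' @param bladder_prob Probability that a phantom includes a bladder sphere
#'   beyond the inlet.
#' @return List of [phantom_spec()] objects.
#' @export
random_phantom_suite <- function(n, seed, length_range = c(20, 45),
                                 radius_range = c(2, 5),
                                 bend_range = c(120, 180),
                                 inner_range = c(2, 4),
                                 outer_range = c(3, 6),
                                 spacing = 0.8, supersampling = 3L,
                                 cyst_prob = 0, bladder_prob = 0) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  specs <- vector("list", n)
  for (i in seq_len(n)) {
    total <- stats::runif(1, length_range[1], length_range[2])
    radius <- stats::runif(1, radius_range[1], radius_range[2])
    bend <- stats::runif(1, bend_range[1], bend_range[2]) * pi / 180
    split <- stats::runif(1, 0.4, 0.6)
    l1 <- total * split
    l2 <- total - l1

    # build in a canonical frame (inlet arm along +z, bend in the yz plane),
    # then apply a random rotation and a small random world offset
    mid <- c(0, 0, 0)
    inlet <- c(0, 0, l1)
    dir2 <- c(0, sin(pi - bend), -cos(pi - bend))
    outlet <- mid + l2 * dir2
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    R <- rotation_matrix(ax, stats::runif(1, 0, 2 * pi))
    shift <- stats::runif(3, -5, 5)
    tp <- function(p) as.numeric(R %*% p) + shift

    cysts <- list()
    if (cyst_prob > 0 && stats::runif(1) < cyst_prob) {
      for (k in seq_len(sample(1:2, 1))) {
        arm <- if (stats::runif(1) < 0.5) list(a = inlet, b = mid) else list(a = mid, b = outlet)
        t_pos <- stats::runif(1, 0.25, 0.75)
        arm_len <- sqrt(sum((arm$b - arm$a)^2))
        r_c <- min(radius * stats::runif(1, 0.4, 0.8),
                   0.8 * t_pos * arm_len, 0.8 * (1 - t_pos) * arm_len)
        centre <- arm$a + t_pos * (arm$b - arm$a)
        off <- stats::rnorm(3)
        off <- off / sqrt(sum(off^2)) * stats::runif(1, 0, 0.8 * (radius - r_c))
        cysts[[length(cysts) + 1L]] <- list(centre = tp(centre + off), radius = r_c)
      }
    }
    with_bladder <- bladder_prob > 0 && stats::runif(1) < bladder_prob

    specs[[i]] <- phantom_spec(
      inlet_point = tp(inlet), mid_point = tp(mid), outlet_point = tp(outlet),
      canal_radius = radius,
      inner_thickness = stats::runif(1, inner_range[1], inner_range[2]),
      outer_thickness = stats::runif(1, outer_range[1], outer_range[2]),
      cysts = cysts, include_bladder = with_bladder, bladder_radius = 6,
      spacing = spacing, supersampling = supersampling, seed = seed + i
    )
  }
  specs
}

#' Generate rendered phantom image/label training pairs
#'
#' Draws a randomized phantom suite (half the phantoms carry cysts, some a
#' bladder, so all five labels are represented) and renders each with a
#' distinct noise/bias realisation. The result feeds
#' [train_segmentation()] directly.
#'
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @param length_range Total centreline length range in mm (kept modest so
#'   the anatomy fills the network grid well).
#' @param ... Further arguments passed to [random_phantom_suite()].
#' @return List of `list(image, labels, truth)` entries.
#' @export
phantom_training_set <- function(n, seed, length_range = c(20, 40), ...) {
  specs <- random_phantom_suite(n, seed, length_range = length_range,
                                cyst_prob = 0.5, bladder_prob = 0.3, ...)
  lapply(seq_along(specs), function(i) {
    ph <- generate_phantom(specs[[i]], truth_volumes = "none")
    img <- render_intensity(ph$labels, intensity_model(seed = seed * 1000L + i))
    list(image = img, labels = ph$labels, truth = ph$truth)
  })
}
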