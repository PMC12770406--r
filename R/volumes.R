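#' Label codes used throughout the package
#'
#' The parcellation convention assigns one integer code per anatomical
#' region: 0 = background, 1 = endocervical canal (ECC), 2 = inner stroma /
#' subglandular zone (SGZ), 3 = outer stroma (OS), 4 = cyst, 5 = bladder.
#'
#' @format Named integer vector mapping region names to codes.
#' @export
cervix_labels <- c(
  background   = 0L,
  canal        = 1L,
  inner_stroma = 2L,
  outer_stroma = 3L,
  cyst         = 4L,
  bladder      = 5L
)

#' Construct a label volume
#'
#' A label volume is the package's central currency: a 3D integer grid of
#' anatomical label codes together with its voxel spacing and a 4x4
#' voxel-to-world affine in millimetres (RAS+). All landmarks and
#' measurements downstream are expressed in world millimetres, never voxel
#' indices, so results are invariant to grid orientation.
#'
#' @param voxels 3D array of integer label codes in `0..5`.
#' @param spacing Numeric length-3 voxel spacing in mm. If `NULL`, derived
#'   from the affine column norms.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices to mm).
#'   If `NULL`, a diagonal affine built from `spacing` with origin 0.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing = NULL, affine = NULL) {
  geom <- resolve_geometry(dim(voxels), spacing, affine)
  storage.mode(voxels) <- "integer"
  check_label_codes(voxels)
  structure(
    list(voxels = voxels, spacing = geom$spacing, affine = geom$affine),
    class = "label_volume"
  )
}

#' Construct an intensity volume
#'
#' Carrier for T2w-like images; identical geometry conventions to
#' [label_volume()] but with real-valued, finite intensities.
#'
#' @inheritParams label_volume
#' @param voxels 3D array of finite intensities.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = NULL, affine = NULL) {
  geom <- resolve_geometry(dim(voxels), spacing, affine)
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels))) {
    stop("image_volume: intensities must be finite", call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing = geom$spacing, affine = geom$affine),
    class = "image_volume"
  )
}

resolve_geometry <- function(dims, spacing, affine) {
  if (length(dims) != 3L) stop("voxels must be a 3D array", call. = FALSE)
  if (is.null(affine)) {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    spacing <- rep_len(as.numeric(spacing), 3L)
    affine <- diag(c(spacing, 1))
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine))) {
    stop("affine must be a finite 4x4 matrix", call. = FALSE)
  }
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible", call. = FALSE)
  derived <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (is.null(spacing)) {
    spacing <- derived
  } else {
    spacing <- rep_len(as.numeric(spacing), 3L)
    if (max(abs(spacing - derived)) > 1e-4) {
      stop("spacing inconsistent with affine column norms", call. = FALSE)
    }
  }
  if (any(spacing <= 0)) stop("spacing must be strictly positive", call. = FALSE)
  list(spacing = spacing, affine = affine)
}

check_label_codes <- function(voxels) {
  r <- range(voxels)
  if (r[1] < 0L || r[2] > 5L) {
    bad <- unique(voxels[voxels < 0L | voxels > 5L])
    stop("unknown label code(s): ", paste(sort(bad), collapse = ", "),
         " (valid codes are 0..5)", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  tab <- table(factor(x$voxels, levels = 0:5,
                      labels = names(cervix_labels)))
  present <- tab[tab > 0]
  cat("  labels: ", paste(names(present), present, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, intensity range [", signif(min(x$voxels), 4), ", ",
      signif(max(x$voxels), 4), "]\n", sep = "")
  invisible(x)
}

#' Physical volume of one voxel in cubic millimetres
#' @param vol A `label_volume` or `image_volume`.
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(vol) {
  abs(det(vol$affine[1:3, 1:3]))
}

# Map 0-based voxel indices (n x 3) to world mm coordinates (n x 3).
voxel_to_world <- function(vol, idx0) {
  idx0 <- matrix(as.numeric(idx0), ncol = 3L)
  h <- cbind(idx0, 1)
  out <- h %*% t(vol$affine)
  out[, 1:3, drop = FALSE]
}

# Map world mm points (n x 3) to continuous 0-based voxel coordinates.
world_to_voxel <- function(vol, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  h <- cbind(pts, 1)
  out <- h %*% t(solve(vol$affine))
  out[, 1:3, drop = FALSE]
}

# 0-based voxel indices (n x 3) of all voxels whose label is in `codes`.
label_indices <- function(vol, codes) {
  w <- which(array(vol$voxels %in% codes, dim(vol$voxels)), arr.ind = TRUE)
  if (length(w) == 0L) return(matrix(numeric(0), ncol = 3L))
  unname(w) - 1
}

same_grid <- function(a, b, tol = 1e-5) {
  all(dim(a$voxels) == dim(b$voxels)) &&
    max(abs(a$affine - b$affine)) <= tol
}
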