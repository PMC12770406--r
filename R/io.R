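#' Read a label volume from a NIfTI-1 file
#'
#' Reads a multi-label parcellation volume, taking spacing and the
#' voxel-to-world affine from the NIfTI header. Data must be integer-valued
#' (within 1e-6) and restricted to the package's label codes 0..5
#' (see [cervix_labels]).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) != 3L) stop("expected a 3D volume", call. = FALSE)
  rounded <- round(vox)
  if (max(abs(vox - rounded)) > 1e-6) {
    stop("non-integer label data in ", path, call. = FALSE)
  }
  aff <- nifti_affine(img)
  label_volume(array(as.integer(rounded), dim(vox)), affine = aff)
}

#' Write a label volume to a NIfTI-1 file
#'
#' Writes the voxel grid and affine; a JSON sidecar (`<path>.json`) records
#' the label-code table so downstream tools can interpret the codes.
#'
#' @param vol A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param sidecar Write the label-table JSON sidecar (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_label_volume <- function(vol, path, sidecar = TRUE) {
  stopifnot(inherits(vol, "label_volume"))
  write_nifti_with_affine(vol$voxels, vol$spacing, vol$affine, path)
  if (isTRUE(sidecar)) {
    jsonlite::write_json(
      list(labels = as.list(cervix_labels), units = "mm", orientation = "RAS"),
      paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(path)
}

#' Read an intensity volume from a NIfTI-1 file
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume()].
#' @export
read_image_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) != 3L) stop("expected a 3D volume", call. = FALSE)
  image_volume(array(as.double(vox), dim(vox)), affine = nifti_affine(img))
}

#' Write an intensity volume to a NIfTI-1 file
#' @param vol An [image_volume()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_image_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  write_nifti_with_affine(vol$voxels, vol$spacing, vol$affine, path)
  invisible(path)
}

nifti_affine <- function(img) {
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = c(4L, 4L))
  aff
}

write_nifti_with_affine <- function(voxels, spacing, affine, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  if (file.access(dir, mode = 2L) != 0L) {
    stop("directory not writable: ", dir, call. = FALSE)
  }
  img <- RNifti::asNifti(voxels)
  RNifti::pixdim(img) <- spacing
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
}

#' Resample a label volume to a new isotropic spacing
#'
#' Nearest-neighbour resampling onto an isotropic grid covering the same
#' world extent. Labels are never interpolated, so the label set can only
#' shrink, never grow.
#'
#' @param vol A [label_volume()].
#' @param new_spacing Target isotropic spacing in mm (scalar, > 0).
#' @return A [label_volume()] on the new grid.
#' @export
resample_labels <- function(vol, new_spacing) {
  stopifnot(inherits(vol, "label_volume"))
  geom <- resampled_geometry(vol, new_spacing)
  M <- solve(vol$affine) %*% geom$affine
  out <- resample_affine_cpp(as.double(vol$voxels), dim(vol$voxels), M,
                             geom$dims, 0L, 0)
  label_volume(array(as.integer(out), geom$dims), affine = geom$affine)
}

#' Resample an intensity volume to a new isotropic spacing
#'
#' Trilinear resampling counterpart of [resample_labels()].
#'
#' @param vol An [image_volume()].
#' @param new_spacing Target isotropic spacing in mm (scalar, > 0).
#' @param background Fill value for samples outside the source grid.
#' @return An [image_volume()] on the new grid.
#' @export
resample_image <- function(vol, new_spacing, background = 0) {
  stopifnot(inherits(vol, "image_volume"))
  geom <- resampled_geometry(vol, new_spacing)
  M <- solve(vol$affine) %*% geom$affine
  out <- resample_affine_cpp(vol$voxels, dim(vol$voxels), M, geom$dims, 1L,
                             background)
  image_volume(array(out, geom$dims), affine = geom$affine)
}

resampled_geometry <- function(vol, new_spacing) {
  if (!is.numeric(new_spacing) || length(new_spacing) != 1L ||
      !is.finite(new_spacing) || new_spacing <= 0) {
    stop("new_spacing must be a positive scalar", call. = FALSE)
  }
  dims <- dim(vol$voxels)
  directions <- sweep(vol$affine[1:3, 1:3], 2, vol$spacing, "/")
  new_dims <- pmax(1L, as.integer(ceiling(dims * vol$spacing / new_spacing)))
  A3 <- directions * new_spacing
  # align the world-space corner of voxel (-0.5,-0.5,-0.5) across grids
  corner <- vol$affine %*% c(-0.5, -0.5, -0.5, 1)
  origin <- corner[1:3] - A3 %*% rep(-0.5, 3)
  affine <- rbind(cbind(A3, origin), c(0, 0, 0, 1))
  list(dims = new_dims, affine = affine)
}
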