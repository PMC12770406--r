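#' Locate the canal end interfaces (internal and external os)
#'
#' The inlet and outlet regions of interest are localised as interfaces
#' between the canal (including cysts) and background: canal/cyst voxels
#' with at least one face-adjacent (6-neighbourhood) background voxel,
#' together with the background voxels face-adjacent to canal/cyst, grouped
#' into 26-connected components. Taking both sides of the voxelized
#' interface keeps the ROI centroid on the continuous end surface instead
#' of half a voxel inside it. The two largest components are taken as the
#' canal ends. Voxels outside the grid count as background.
#'
#' Which end is the inlet (internal os) cannot be inferred from the label
#' map alone; by default the end with the more superior world coordinate is
#' called the inlet (the internal os lies toward the uterine cavity,
#' superior in supine imaging). This is overridable via `inlet`.
#'
#' @param vol A [label_volume()] containing the canal label.
#' @param inlet Disambiguation rule: `"superior"` (default), `"inferior"`,
#'   or `"nearest-to"` with `inlet_point` supplied.
#' @param inlet_point World mm point used when `inlet = "nearest-to"`.
#' @return List with `inlet_roi` and `outlet_roi`, each a matrix of 0-based
#'   voxel indices (one row per voxel).
#' @export
locate_end_interfaces <- function(vol, inlet = c("superior", "inferior", "nearest-to"),
                                  inlet_point = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  inlet <- match.arg(inlet)
  dims <- dim(vol$voxels)
  canal_n <- sum(vol$voxels == cervix_labels[["canal"]])
  if (canal_n == 0) stop("no canal voxels in volume", call. = FALSE)
  if (canal_n < 20) {
    stop("canal label too small (", canal_n, " voxels; need >= 20)",
         call. = FALSE)
  }

  mask <- vol$voxels == cervix_labels[["canal"]] |
    vol$voxels == cervix_labels[["cyst"]]
  inner_side <- mask & face_adjacent_to(vol$voxels == 0L)
  outer_side <- vol$voxels == 0L & face_adjacent_to(mask, outside = FALSE)
  interface <- inner_side | outer_side
  if (!any(inner_side)) {
    stop("no end interfaces: canal has no background contact (closed/capped canal)",
         call. = FALSE)
  }

  comp <- label_components_cpp(as.logical(interface), dims, 26L)
  n_comp <- attr(comp, "n_components")
  if (n_comp < 2) {
    stop("fewer than two end-interface components (closed canal / capped end)",
         call. = FALSE)
  }
  comp <- array(comp, dims)
  sizes <- tabulate(comp[comp > 0], nbins = n_comp)
  ord <- order(sizes, decreasing = TRUE)
  ids <- ord[1:2]
  roi1 <- unname(which(comp == ids[1], arr.ind = TRUE)) - 1
  roi2 <- unname(which(comp == ids[2], arr.ind = TRUE)) - 1

  # guard against ambiguous geometry where the two candidate ends nearly meet
  w1 <- voxel_to_world(vol, roi1)
  w2 <- voxel_to_world(vol, roi2)
  if (min_pointset_distance(w1, w2) < 2 * min(vol$spacing)) {
    stop("ambiguous end interfaces: two largest components are touching",
         call. = FALSE)
  }

  c1 <- colMeans(w1)
  c2 <- colMeans(w2)
  first_is_inlet <- switch(inlet,
    superior = c1[3] >= c2[3],
    inferior = c1[3] < c2[3],
    `nearest-to` = {
      if (is.null(inlet_point)) {
        stop("inlet = \"nearest-to\" requires inlet_point", call. = FALSE)
      }
      sum((c1 - inlet_point)^2) <= sum((c2 - inlet_point)^2)
    }
  )
  if (first_is_inlet) {
    list(inlet_roi = roi1, outlet_roi = roi2)
  } else {
    list(inlet_roi = roi2, outlet_roi = roi1)
  }
}

# TRUE where any of the six face neighbours satisfies `target` (a logical
# array); the outside of the grid counts as background.
face_adjacent_to <- function(target, outside = TRUE) {
  dims <- dim(target)
  out <- array(FALSE, dims)
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      out <- out | shift_array(target, axis, dir, fill = outside)
    }
  }
  out
}

# Shift a 3D array by one voxel along `axis`; vacated entries take `fill`.
# dir = +1 brings the value of the (i+1)th slice to position i.
shift_array <- function(a, axis, dir, fill) {
  dims <- dim(a)
  out <- array(fill, dims)
  n <- dims[axis]
  src <- if (dir > 0) 2:n else 1:(n - 1)
  dst <- if (dir > 0) 1:(n - 1) else 2:n
  idx_src <- list(quote(expr =), quote(expr =), quote(expr =))
  idx_dst <- idx_src
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst,
                          list(do.call(`[`, c(list(a), idx_src)))))
  out
}

min_pointset_distance <- function(a, b) {
  # both small (end-interface discs); direct pairwise computation
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Centre-point of a voxel ROI
#'
#' The arithmetic mean of the world coordinates of the ROI voxel centres.
#'
#' @param roi Matrix of 0-based voxel indices (one row per voxel).
#' @param vol The [label_volume()] providing the grid geometry.
#' @return World mm point (length 3).
#' @export
compute_centrepoint <- function(roi, vol) {
  if (is.null(roi) || nrow(roi) == 0) stop("empty ROI", call. = FALSE)
  colMeans(voxel_to_world(vol, roi))
}

#' Canal midpoint landmark
#'
#' The mean world coordinate of all canal-label voxels (canal label only;
#' cysts are not included). For a curved canal this point can lie off the
#' canal axis; no projection is applied.
#'
#' @param vol A [label_volume()].
#' @return World mm point (length 3).
#' @export
compute_midpoint <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  idx <- label_indices(vol, cervix_labels[["canal"]])
  if (nrow(idx) == 0) stop("no canal voxels in volume", call. = FALSE)
  colMeans(voxel_to_world(vol, idx))
}

#' Two-line cervical length
#'
#' The clinical two-line measurement: the sum of the straight-line
#' distances inlet -> midpoint and midpoint -> outlet.
#'
#' @param inlet,midpoint,outlet World mm points.
#' @return Length in mm.
#' @export
measure_cervical_length <- function(inlet, midpoint, outlet) {
  pts <- c(inlet, midpoint, outlet)
  if (length(pts) != 9 || !all(is.finite(pts))) {
    stop("landmarks must be three finite 3D points", call. = FALSE)
  }
  sqrt(sum((inlet - midpoint)^2)) + sqrt(sum((midpoint - outlet)^2))
}

#' Canal diameter at a landmark level
#'
#' Measures the canal diameter at `centre` in the measurement plane: rays
#' are marched from the centre in both directions along
#' `normalize(plane_normal x axis_direction)` in 0.1 mm steps with
#' nearest-neighbour label sampling, stopping at the first sample labelled
#' inner stroma or background (the boundaries defined by the inner layer).
#' The diameter is the distance between the two stop points.
#'
#' @param vol A [label_volume()].
#' @param centre World mm point inside the canal (or a cyst).
#' @param axis_direction Unit vector along the local canal axis.
#' @param plane_normal Unit normal of the measurement plane.
#' @param step Ray marching step in mm.
#' @param axial_tolerance Axial staircase tolerance in mm: a sample only
#'   stops the ray if shifting it by this amount along `axis_direction`
#'   (either way) does not land back in canal/cyst. Compensates the
#'   half-voxel staircase of the voxelized canal end surfaces, which is
#'   axial and unrelated to the radial inner-layer boundary being
#'   measured. `NULL` defaults to half the largest voxel spacing; 0
#'   disables.
#' @return Diameter in mm.
#' @export
measure_diameter <- function(vol, centre, axis_direction, plane_normal,
                             step = 0.1, axial_tolerance = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  if (is.null(axial_tolerance)) axial_tolerance <- max(vol$spacing) / 2
  d <- cross3(plane_normal, axis_direction)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-8) {
    stop("axis_direction and plane_normal are parallel; cannot form ray direction",
         call. = FALSE)
  }
  d <- d / nd
  start_label <- sample_label(vol, matrix(centre, 1))
  if (!start_label %in% cervix_labels[c("canal", "cyst")]) {
    stop("centre outside canal", call. = FALSE)
  }
  axis_step <- axis_direction / sqrt(sum(axis_direction^2)) * axial_tolerance
  stop_pos <- lapply(list(d, -d), function(dir) {
    march_ray(vol, centre, dir, step, axis_step)
  })
  sqrt(sum((stop_pos[[1]] - stop_pos[[2]])^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

sample_label <- function(vol, pts) {
  v <- round(world_to_voxel(vol, pts))
  dims <- dim(vol$voxels)
  out <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    if (any(v[i, ] < 0) || any(v[i, ] > dims - 1)) {
      out[i] <- NA_integer_
    } else {
      out[i] <- vol$voxels[v[i, 1] + 1, v[i, 2] + 1, v[i, 3] + 1]
    }
  }
  out
}

march_ray <- function(vol, centre, dir, step, axis_step = c(0, 0, 0)) {
  stop_codes <- cervix_labels[c("background", "inner_stroma")]
  inside_codes <- cervix_labels[c("canal", "cyst")]
  use_tol <- any(axis_step != 0)
  max_steps <- ceiling(sum(dim(vol$voxels) * vol$spacing) / step) + 1L
  for (s in seq_len(max_steps)) {
    p <- centre + s * step * dir
    lab <- sample_label(vol, matrix(p, 1))
    if (is.na(lab)) {
      stop("diameter ray exited the grid before reaching a boundary",
           call. = FALSE)
    }
    if (lab %in% stop_codes) {
      if (use_tol) {
        near <- sample_label(vol, rbind(p + axis_step, p - axis_step))
        if (any(!is.na(near) & near %in% inside_codes)) next
      }
      return(p)
    }
  }
  stop("diameter ray exited the grid before reaching a boundary", call. = FALSE)
}

#' Run the full automated biometry pipeline on a label volume
#'
#' Extracts the inlet/outlet/midpoint landmarks, computes the two-line
#' cervical length, fits the measurement plane through the three landmarks
#' (falling back to the world sagittal plane when they are collinear), and
#' measures the inlet and outlet canal diameters in that plane at their
#' corresponding centre-point levels.
#'
#' @inheritParams locate_end_interfaces
#' @return An object of class `biometry_result` with elements `landmarks`
#'   (inlet/outlet centres, midpoint, ROIs), `cervical_length_mm`,
#'   `inlet_diameter_mm`, `outlet_diameter_mm` and `measurement_plane`.
#' @export
run_biometry <- function(vol, inlet = c("superior", "inferior", "nearest-to"),
                         inlet_point = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  inlet <- match.arg(inlet)
  rois <- locate_end_interfaces(vol, inlet = inlet, inlet_point = inlet_point)
  inlet_centre <- compute_centrepoint(rois$inlet_roi, vol)
  outlet_centre <- compute_centrepoint(rois$outlet_roi, vol)
  midpoint <- compute_midpoint(vol)
  length_mm <- measure_cervical_length(inlet_centre, midpoint, outlet_centre)

  normal <- cross3(midpoint - inlet_centre, outlet_centre - midpoint)
  nn <- sqrt(sum(normal^2))
  scale <- max(sqrt(sum((outlet_centre - inlet_centre)^2)), 1)
  if (nn < 1e-6 * scale^2) {
    # collinear landmarks: fall back to the world sagittal plane
    normal <- c(1, 0, 0)
  } else {
    normal <- normal / nn
  }
  plane_point <- (inlet_centre + midpoint + outlet_centre) / 3

  inlet_axis <- normalize3(midpoint - inlet_centre)
  outlet_axis <- normalize3(outlet_centre - midpoint)
  # the end-interface centroid lies within half a voxel of the open end, so
  # its nearest voxel can fall just outside the canal; nudge the marching
  # start sub-voxel inward along the canal axis onto a canal/cyst voxel
  inlet_start <- nudge_into_canal(vol, inlet_centre, inlet_axis)
  outlet_start <- nudge_into_canal(vol, outlet_centre, -outlet_axis)
  inlet_diam <- measure_diameter(vol, inlet_start, inlet_axis, normal)
  outlet_diam <- measure_diameter(vol, outlet_start, outlet_axis, normal)

  structure(
    list(
      landmarks = list(inlet_centre = inlet_centre,
                       outlet_centre = outlet_centre,
                       midpoint = midpoint,
                       inlet_roi = rois$inlet_roi,
                       outlet_roi = rois$outlet_roi),
      cervical_length_mm = length_mm,
      inlet_diameter_mm = inlet_diam,
      outlet_diameter_mm = outlet_diam,
      measurement_plane = list(point = plane_point, normal = normal),
      parameters = list(inlet_rule = inlet)
    ),
    class = "biometry_result"
  )
}

# Step a landmark inward along `direction` (toward the canal interior) in
# 0.1 mm increments until its nearest voxel is canal or cyst, then half a
# voxel further so the diameter ray clears the staircase of the voxelized
# end surface. Searches up to two voxel spacings.
nudge_into_canal <- function(vol, centre, direction, step = 0.1) {
  inside <- cervix_labels[c("canal", "cyst")]
  extra <- max(vol$spacing) / 2
  for (t in seq(0, 2 * max(vol$spacing), by = step)) {
    p <- centre + t * direction
    lab <- sample_label(vol, matrix(p, 1))
    if (!is.na(lab) && lab %in% inside) {
      deeper <- centre + (t + extra) * direction
      lab2 <- sample_label(vol, matrix(deeper, 1))
      if (!is.na(lab2) && lab2 %in% inside) return(deeper)
      return(p)
    }
  }
  stop("landmark centre could not be placed inside the canal", call. = FALSE)
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize zero vector", call. = FALSE)
  v / n
}

#' @export
print.biometry_result <- function(x, ...) {
  cat("<biometry_result>\n")
  cat("  cervical length: ", round(x$cervical_length_mm, 2), " mm\n", sep = "")
  cat("  inlet diameter:  ", round(x$inlet_diameter_mm, 2), " mm\n", sep = "")
  cat("  outlet diameter: ", round(x$outlet_diameter_mm, 2), " mm\n", sep = "")
  invisible(x)
}

#' Serialise a biometry result to JSON
#'
#' @param result A `biometry_result`.
#' @param path Output JSON path.
#' @param input Optional input path recorded as provenance.
#' @return Invisibly, `path`.
#' @export
write_biometry_json <- function(result, path, input = NULL) {
  stopifnot(inherits(result, "biometry_result"))
  payload <- list(
    landmarks_mm = list(
      inlet = unname(result$landmarks$inlet_centre),
      midpoint = unname(result$landmarks$midpoint),
      outlet = unname(result$landmarks$outlet_centre)
    ),
    measurements_mm = list(
      cervical_length = result$cervical_length_mm,
      inlet_diameter = result$inlet_diameter_mm,
      outlet_diameter = result$outlet_diameter_mm
    ),
    measurement_plane = list(
      point = unname(result$measurement_plane$point),
      normal = unname(result$measurement_plane$normal)
    ),
    provenance = list(
      input = input,
      package = "cervimetry",
      version = as.character(utils::packageVersion("cervimetry")),
      parameters = result$parameters,
      coordinate_convention = "RAS mm"
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
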