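test_that("end interfaces sit at the tube ends of a straight phantom", {
  ph <- straight_phantom()
  rois <- locate_end_interfaces(ph$labels)
  ci <- compute_centrepoint(rois$inlet_roi, ph$labels)
  co <- compute_centrepoint(rois$outlet_roi, ph$labels)
  # default rule: inlet is the superior end (+z here)
  expect_points_close(ci, c(0, 0, 15), 2 * 0.8)
  expect_points_close(co, c(0, 0, -15), 2 * 0.8)
  expect_gt(nrow(rois$inlet_roi), 0)
  # the two ROIs are disjoint
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_length(intersect(key(rois$inlet_roi), key(rois$outlet_roi)), 0)

  # rule overrides
  swapped <- locate_end_interfaces(ph$labels, inlet = "inferior")
  expect_points_close(compute_centrepoint(swapped$inlet_roi, ph$labels),
                      c(0, 0, -15), 2 * 0.8)
  near <- locate_end_interfaces(ph$labels, inlet = "nearest-to",
                                inlet_point = c(0, 0, -14))
  expect_points_close(compute_centrepoint(near$inlet_roi, ph$labels),
                      c(0, 0, -15), 2 * 0.8)
})

test_that("a fully enclosed canal has no end interfaces", {
  # canal ring enclosed by inner stroma on all sides
  vox <- array(0L, c(16, 16, 16))
  vox[5:12, 5:12, 5:12] <- 2L
  vox[7:10, 7:10, 7:10] <- 1L
  vol <- label_volume(vox)
  expect_error(locate_end_interfaces(vol), "closed")
})

test_that("too small or absent canal is rejected", {
  vol <- label_volume(array(0L, c(8, 8, 8)))
  expect_error(locate_end_interfaces(vol), "no canal")
  vox <- array(0L, c(8, 8, 8))
  vox[4, 4, 4] <- 1L
  expect_error(locate_end_interfaces(label_volume(vox)), "too small")
})

test_that("a cyst flush against the inlet opening joins the inlet ROI", {
  spec <- phantom_spec(c(0, 0, 12), c(0, 0, 0), c(0, 0, -12), canal_radius = 3,
                       cysts = list(list(centre = c(0, 0, 10.5), radius = 1.5)))
  ph <- generate_phantom(spec, truth_volumes = "none")
  rois <- locate_end_interfaces(ph$labels)
  labs <- apply(rois$inlet_roi + 1, 1, function(ix) {
    ph$labels$voxels[ix[1], ix[2], ix[3]]
  })
  expect_true(any(labs == 4))
})

test_that("centre-points are arithmetic means of ROI voxel centres", {
  vol <- label_volume(array(1L, c(4, 4, 4)))
  roi <- rbind(c(0, 0, 0), c(0, 2, 0))
  expect_equal(compute_centrepoint(roi, vol), c(0, 1, 0))
  expect_equal(compute_centrepoint(rbind(c(1, 2, 3)), vol), c(1, 2, 3))
  expect_error(compute_centrepoint(matrix(numeric(0), ncol = 3), vol), "empty")
})

test_that("the midpoint is the mean canal coordinate", {
  ph <- straight_phantom()
  expect_points_close(compute_midpoint(ph$labels), c(0, 0, 0), 0.5 * 0.8)

  single <- array(0L, c(8, 8, 8))
  single[3, 5, 2] <- 1L
  expect_equal(compute_midpoint(label_volume(single)), c(2, 4, 1))
  expect_error(compute_midpoint(label_volume(array(0L, c(4, 4, 4)))),
               "no canal")

  # bent phantom: the centroid lies off the canal axis, pulled into the bend
  bent <- bent_phantom()
  mid <- compute_midpoint(bent$labels)
  d_axis <- min(
    cervimetry:::point_segment_distance(mid, c(0, 0, 0), c(0, 10, 10)),
    cervimetry:::point_segment_distance(mid, c(0, 10, 10), c(0, 20, 10))
  )
  expect_gt(d_axis, 0.5)
})

test_that("the two-line length follows from the landmarks exactly", {
  expect_equal(measure_cervical_length(c(0, 0, 0), c(0, 0, 15), c(0, 0, 30)), 30)
  expect_equal(measure_cervical_length(c(0, 0, 0), c(0, 10, 10), c(0, 20, 10)),
               10 * sqrt(2) + 10)
  # coincident midpoint and inlet degenerates to the straight distance
  expect_equal(measure_cervical_length(c(1, 2, 3), c(1, 2, 3), c(1, 2, 10)), 7)
  expect_error(measure_cervical_length(c(0, 0, NA), c(0, 0, 0), c(0, 0, 1)),
               "finite")
})

test_that("diameters recover the canal width and scale with radius", {
  ph <- straight_phantom()
  d1 <- measure_diameter(ph$labels, c(0, 0, 10), c(0, 0, 1), c(1, 0, 0))
  expect_equal(d1, 6, tolerance = 2 * 0.8 / 6)

  spec2 <- phantom_spec(c(0, 0, 15), c(0, 0, 0), c(0, 0, -15), canal_radius = 6,
                        spacing = 0.8)
  ph2 <- generate_phantom(spec2, truth_volumes = "none")
  d2 <- measure_diameter(ph2$labels, c(0, 0, 10), c(0, 0, 1), c(1, 0, 0))
  expect_equal(d2 / d1, 2, tolerance = 2 * 0.8 / 6)

  # centre in the outer stroma violates the contract
  expect_error(
    measure_diameter(ph$labels, c(0, 3 + 3 + 2, 0), c(0, 0, 1), c(1, 0, 0)),
    "outside canal"
  )
  # parallel axis and normal cannot define a ray
  expect_error(
    measure_diameter(ph$labels, c(0, 0, 0), c(0, 0, 1), c(0, 0, 1)),
    "parallel"
  )
})

test_that("run_biometry recovers the default phantom within 2 voxels", {
  ph <- straight_phantom()
  b <- run_biometry(ph$labels)
  expect_equal(b$cervical_length_mm, 30, tolerance = 1.6 / 30)
  expect_equal(b$inlet_diameter_mm, 6, tolerance = 1.6 / 6)
  expect_equal(b$outlet_diameter_mm, 6, tolerance = 1.6 / 6)
  # stored landmarks reproduce the reported length exactly
  expect_equal(
    measure_cervical_length(b$landmarks$inlet_centre, b$landmarks$midpoint,
                            b$landmarks$outlet_centre),
    b$cervical_length_mm
  )
  # collinear landmarks fall back to the world sagittal plane
  expect_equal(abs(b$measurement_plane$normal), c(1, 0, 0), tolerance = 1e-6)
})

test_that("measurements are invariant to rigid motion of the phantom", {
  base <- phantom_spec(c(0, 0, 15), c(0, 0, 0), c(0, 0, -15), canal_radius = 3,
                       spacing = 0.8)
  b0 <- run_biometry(generate_phantom(base, truth_volumes = "none")$labels)

  th <- 45 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  shift <- c(7.3, -4.1, 2.9)
  tp <- function(p) as.numeric(R %*% p) + shift
  rot <- phantom_spec(tp(c(0, 0, 15)), tp(c(0, 0, 0)), tp(c(0, 0, -15)),
                      canal_radius = 3, spacing = 0.8)
  br <- run_biometry(generate_phantom(rot, truth_volumes = "none")$labels,
                     inlet = "nearest-to", inlet_point = tp(c(0, 0, 15)))
  expect_lt(abs(br$cervical_length_mm - b0$cervical_length_mm), 0.8)
  expect_lt(abs(br$inlet_diameter_mm - b0$inlet_diameter_mm), 0.8)
  expect_lt(abs(br$outlet_diameter_mm - b0$outlet_diameter_mm), 0.8)
})

test_that("increasing canal radius strictly increases measured diameters", {
  diam <- sapply(c(2, 3, 4, 5), function(r) {
    spec <- phantom_spec(c(0, 0, 14), c(0, 0, 0), c(0, 0, -14), canal_radius = r,
                         spacing = 0.8)
    b <- run_biometry(generate_phantom(spec, truth_volumes = "none")$labels)
    c(b$inlet_diameter_mm, b$outlet_diameter_mm)
  })
  expect_true(all(diff(diam[1, ]) > 0))
  expect_true(all(diff(diam[2, ]) > 0))
})

test_that("biometry results serialise to JSON with landmarks in mm", {
  ph <- straight_phantom()
  b <- run_biometry(ph$labels)
  path <- file.path(withr::local_tempdir(), "biometry.json")
  write_biometry_json(b, path, input = "phantom")
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$measurements_mm$cervical_length, b$cervical_length_mm)
  expect_equal(unname(unlist(back$landmarks_mm$inlet)),
               unname(b$landmarks$inlet_centre))
  expect_equal(back$provenance$coordinate_convention, "RAS mm")
})
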