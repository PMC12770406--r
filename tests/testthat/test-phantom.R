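test_that("phantom truth reproduces the analytic two-line geometry", {
  straight <- phantom_spec(c(0, 0, -15), c(0, 0, 0), c(0, 0, 15),
                           canal_radius = 3)
  tr <- generate_phantom(straight, truth_volumes = "none")$truth
  expect_equal(tr$length_mm, 30)
  expect_equal(tr$inlet_diameter_mm, 6)
  expect_equal(tr$outlet_diameter_mm, 6)

  bent <- phantom_spec(c(0, 0, 0), c(0, 10, 10), c(0, 20, 10), canal_radius = 3)
  tr2 <- generate_phantom(bent, truth_volumes = "none")$truth
  expect_equal(tr2$length_mm, 10 * sqrt(2) + 10, tolerance = 1e-12)
  expect_false(tr2$collinear)
  # length never shorter than the straight inlet-outlet distance
  expect_gte(tr2$length_mm, sqrt(sum((c(0, 20, 10) - c(0, 0, 0))^2)))
})

test_that("rasterized canal volume matches pi r^2 L at fine spacing", {
  spec <- phantom_spec(c(0, 0, 15), c(0, 0, 0), c(0, 0, -15),
                       canal_radius = 5, spacing = 0.4, supersampling = 5L)
  ph <- generate_phantom(spec)
  analytic <- pi * 25 * 30
  expect_equal(ph$truth$volumes_mm3[["canal"]], analytic, tolerance = 1e-6)
  counted <- sum(ph$labels$voxels == 1) * voxel_volume_mm3(ph$labels)
  expect_lt(abs(counted - analytic) / analytic, 0.02)
})

test_that("quadrature volumes agree with the closed form on straight phantoms", {
  spec <- phantom_spec(c(0, 0, 12), c(0, 0, 0), c(0, 0, -12), canal_radius = 3)
  exact <- generate_phantom(spec, truth_volumes = "auto")$truth$volumes_mm3
  quad <- generate_phantom(spec, truth_volumes = "quadrature")$truth$volumes_mm3
  for (nm in c("canal", "inner_stroma", "outer_stroma")) {
    expect_lt(abs(quad[[nm]] - exact[[nm]]) / exact[[nm]], 0.005)
  }
})

test_that("label volumes converge to analytic values as spacing shrinks", {
  mk <- function(sp) {
    spec <- phantom_spec(c(0, 0, 15), c(0, 0, 0), c(0, 0, -15),
                         canal_radius = 3, spacing = sp)
    generate_phantom(spec)
  }
  coarse <- mk(0.8)
  fine <- mk(0.4)
  rel_err <- function(ph) {
    counted <- sum(ph$labels$voxels == 1) * voxel_volume_mm3(ph$labels)
    abs(counted - ph$truth$volumes_mm3[["canal"]]) / ph$truth$volumes_mm3[["canal"]]
  }
  e_coarse <- rel_err(coarse)
  e_fine <- rel_err(fine)
  expect_lt(e_coarse, 0.05)
  expect_lt(e_fine, 0.02)
  expect_gt(e_coarse, e_fine)
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(c(0, 0, 10), c(0, 0, 0), c(0, 0, -10),
                            canal_radius = -1), "positive")
  # cyst sticking out of the canal tube
  expect_error(
    phantom_spec(c(0, 0, 10), c(0, 0, 0), c(0, 0, -10), canal_radius = 2,
                 cysts = list(list(centre = c(1.5, 0, 0), radius = 1))),
    "outside the canal"
  )
  # geometry larger than a forced grid
  expect_error(
    phantom_spec(c(0, 0, 20), c(0, 0, 0), c(0, 0, -20), grid_size = 16),
    "exceeds"
  )
})

test_that("cysts overwrite canal voxels and stay mutually exclusive", {
  spec <- phantom_spec(c(0, 0, 12), c(0, 0, 0), c(0, 0, -12), canal_radius = 3,
                       cysts = list(list(centre = c(0, 0, 5), radius = 1.5)))
  ph <- generate_phantom(spec)
  expect_gt(sum(ph$labels$voxels == 4), 0)
  expect_equal(ph$truth$volumes_mm3[["cyst"]], 4 / 3 * pi * 1.5^3)
  # cyst + canal label volume matches the cyst-free canal tube
  expect_equal(ph$truth$volumes_mm3[["canal"]] + ph$truth$volumes_mm3[["cyst"]],
               pi * 9 * 24)
})

test_that("noise-free bias-free rendering is exactly piecewise constant", {
  ph <- straight_phantom()
  model <- intensity_model(canal_mix = 0, noise_sd = 0, bias_amplitude = 0)
  img <- render_intensity(ph$labels, model)
  for (code in c(0:3)) {
    vals <- img$voxels[ph$labels$voxels == code]
    expect_equal(unique(vals), unname(model$means[code + 1]))
  }
  # layer contrast ordering: inner stroma darkest, cysts brightest
  expect_lt(mean(img$voxels[ph$labels$voxels == 2]),
            min(mean(img$voxels[ph$labels$voxels == 1]),
                mean(img$voxels[ph$labels$voxels == 3])))
})

test_that("rendering is deterministic given the seed and seed-dependent otherwise", {
  ph <- straight_phantom()
  a <- render_intensity(ph$labels, intensity_model(seed = 5))
  b <- render_intensity(ph$labels, intensity_model(seed = 5))
  d <- render_intensity(ph$labels, intensity_model(seed = 6))
  expect_identical(a$voxels, b$voxels)
  expect_false(identical(a$voxels, d$voxels))
})

test_that("noise averages out over independent realisations", {
  ph <- straight_phantom()
  base <- render_intensity(ph$labels,
                           intensity_model(canal_mix = 0, noise_sd = 0,
                                           bias_amplitude = 0))
  sd_noise <- 0.05
  n_rep <- 100
  acc <- array(0, dim(base$voxels))
  for (s in seq_len(n_rep)) {
    r <- render_intensity(ph$labels,
                          intensity_model(canal_mix = 0, noise_sd = sd_noise,
                                          bias_amplitude = 0, seed = 1000 + s))
    acc <- acc + r$voxels
  }
  avg <- acc / n_rep
  se <- sd_noise / sqrt(n_rep)
  # voxelwise means converge to the noise-free image within 3 SE on average
  expect_lt(mean(abs(avg - base$voxels)), 3 * se)
})

test_that("the random suite respects its parameter ranges", {
  specs <- random_phantom_suite(20, seed = 9)
  lens <- sapply(specs, function(s) {
    sqrt(sum((s$inlet_point - s$mid_point)^2)) +
      sqrt(sum((s$outlet_point - s$mid_point)^2))
  })
  radii <- sapply(specs, function(s) s$canal_radius)
  expect_true(all(lens >= 20 & lens <= 45))
  expect_true(all(radii >= 2 & radii <= 5))
  # suite generation is reproducible
  specs2 <- random_phantom_suite(20, seed = 9)
  expect_equal(specs[[7]]$inlet_point, specs2[[7]]$inlet_point)
})
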