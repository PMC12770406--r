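test_that("laplacian sharpening obeys its limit cases", {
  img <- rendered_phantom()$image
  # alpha = 0 is the identity
  expect_identical(laplacian_sharpen(img, 0)$voxels, img$voxels)
  # constant image is a fixed point for any alpha
  const <- image_volume(array(2.5, c(10, 10, 10)))
  expect_equal(laplacian_sharpen(const, 0.7)$voxels, const$voxels)
  expect_error(laplacian_sharpen(img, -0.1), ">= 0")
})

test_that("sharpening a step edge overshoots next to the edge only", {
  # 1D step along x (0.25 -> 0.75), constant in y/z. Hand-computed
  # 6-neighbour stencil at the two voxels flanking the edge:
  #   lap(low side)  = 4*0.25 + 0.25 + 0.75 - 6*0.25 = +0.5
  #   lap(high side) = 4*0.75 + 0.25 + 0.75 - 6*0.75 = -0.5
  # so with alpha = 0.5: out = 0.25 - 0.25 = 0.0 and 0.75 + 0.25 = 1.0.
  # Corner voxels carry the global min/max so range clamping (to [0, 1])
  # does not clip the interior overshoot.
  vox <- array(0.25, c(12, 6, 6))
  vox[7:12, , ] <- 0.75
  vox[1, 1, 1] <- 0
  vox[12, 6, 6] <- 1
  out <- laplacian_sharpen(image_volume(vox), 0.5)
  profile <- out$voxels[, 3, 3]
  expect_equal(profile[6], 0.0)   # undershoot below the low plateau
  expect_equal(profile[7], 1.0)   # overshoot above the high plateau
  # monotone (flat) away from the edge
  expect_equal(profile[2:5], rep(0.25, 4))
  expect_equal(profile[8:11], rep(0.75, 4))
})

test_that("registering an image to itself gives a near-identity transform", {
  img <- rendered_phantom()$image
  t_self <- register_pair(img, img, "rigid")
  expect_gt(t_self$similarity, 0.99)
  # decompose: rotation angle and translation at the image centre
  A <- t_self$matrix[1:3, 1:3]
  angle <- acos(min(1, max(-1, (sum(diag(A)) - 1) / 2))) * 180 / pi
  expect_lt(angle, 0.1)
  centre_shift <- t_self$matrix %*% c(t_self$centre, 1) - c(t_self$centre, 1)
  expect_lt(sqrt(sum(centre_shift[1:3]^2)), 0.1)
})

test_that("a known rigid offset is recovered within 0.5 mm and 1 degree", {
  img <- rendered_phantom()$image
  shift <- c(3, -2, 1)
  moved <- image_volume(img$voxels, affine = {
    a <- img$affine
    a[1:3, 4] <- a[1:3, 4] + shift
    a
  })
  tr <- register_pair(img, moved, "rigid")
  # mapping fixed -> moving must reproduce the +shift translation
  rec <- tr$matrix %*% c(tr$centre, 1) - c(tr$centre, 1)
  expect_lt(sqrt(sum((rec[1:3] - shift)^2)), 0.5)
  A <- tr$matrix[1:3, 1:3]
  angle <- acos(min(1, max(-1, (sum(diag(A)) - 1) / 2))) * 180 / pi
  expect_lt(angle, 1)
  # applying the transform aligns the images
  expect_gt(tr$similarity, 0.98)
})

test_that("an affine registration recovers a 10% scale change", {
  img <- rendered_phantom()$image
  centre <- as.numeric(img$affine %*% c((dim(img$voxels) - 1) / 2, 1))[1:3]
  scaled_affine <- img$affine
  scaled_affine[1:3, 1:3] <- scaled_affine[1:3, 1:3] * 1.1
  scaled_affine[1:3, 4] <- centre - scaled_affine[1:3, 1:3] %*%
    ((dim(img$voxels) - 1) / 2)
  moved <- image_volume(img$voxels, affine = scaled_affine)
  t_r <- register_pair(img, moved, "rigid")
  tr <- register_pair(img, moved, "affine", init = t_r)
  A <- tr$matrix[1:3, 1:3]
  scales <- svd(A)$d
  expect_true(all(abs(scales - 1.1) < 0.022))
})

test_that("atlas of identical inputs is a fixed point at alpha 0", {
  img <- rendered_phantom()$image
  cfg <- atlas_config(iterations = 2, target_spacing = 0.8, sharpen_alpha = 0,
                      maxit = 150)
  atlas <- build_atlas(list(img, img, img), cfg)
  ref <- resample_image(img, 0.8)
  # compare on the common interior (resampling edges excluded)
  err <- abs(atlas$voxels - ref$voxels)
  expect_lt(stats::quantile(err, 0.99), 0.02)
  expect_error(build_atlas(list(img), cfg), ">= 2")
})

test_that("groupwise averaging of misaligned copies re-aligns the anatomy", {
  base <- rendered_phantom()$image
  set.seed(77)
  shifts <- list(c(2, -3, 1), c(-3, 1, 2), c(1, 2, -3), c(-2, -1, 2))
  images <- c(list(base), lapply(shifts, function(s) {
    a <- base$affine
    a[1:3, 4] <- a[1:3, 4] + s
    image_volume(base$voxels, affine = a)
  }))
  cfg <- atlas_config(iterations = 1, target_spacing = 1.2, sharpen_alpha = 0,
                      maxit = 150)
  atlas <- build_atlas(images, cfg)
  ref <- resample_image(base, 1.2)
  ncc <- function(x) stats::cor(as.numeric(x$voxels), as.numeric(ref$voxels))
  # each misaligned input, resampled without registration, matches worse
  unaligned <- sapply(images[-1], function(im) {
    M <- solve(im$affine) %*% ref$affine
    v <- cervimetry:::resample_affine_cpp(im$voxels, dim(im$voxels), M,
                                          dim(ref$voxels), 1L, 0)
    stats::cor(v, as.numeric(ref$voxels))
  })
  expect_gt(ncc(atlas), max(unaligned))
})

test_that("averaging reduces voxel noise roughly as 1/N", {
  base <- straight_phantom()
  set.seed(99)
  n <- 10
  noisy <- lapply(seq_len(n), function(i) {
    render_intensity(base$labels,
                     intensity_model(canal_mix = 0, noise_sd = 0.05,
                                     bias_amplitude = 0, seed = 500 + i))
  })
  clean <- render_intensity(base$labels,
                            intensity_model(canal_mix = 0, noise_sd = 0,
                                            bias_amplitude = 0))
  avg <- Reduce(`+`, lapply(noisy, function(x) x$voxels)) / n
  var_single <- mean((noisy[[1]]$voxels - clean$voxels)^2)
  var_avg <- mean((avg - clean$voxels)^2)
  expect_equal(var_avg / var_single, 1 / n, tolerance = 0.2)
})
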