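test_that("configuration invariants are enforced", {
  expect_error(unet_config(depth = 3, channels = c(4, 8)), "length")
  expect_error(unet_config(depth = 4, channels = c(2, 4, 8, 16), grid = 20),
               "multiple")
  expect_error(augmentation_config(rotation_deg = 60), "45")
  # the full-scale recipe is constructible
  full <- unet_config(depth = 5, channels = c(32, 64, 128, 256, 512),
                      grid = 128, iterations = 100000)
  expect_equal(full$channels[5], 512L)
})

test_that("parameter count matches an independent hand count at depth 2", {
  cfg <- unet_config(depth = 2, channels = c(4, 8), grid = 16)
  # hand count, block by block:
  # enc1: conv(1->4) 27*1*4+4, conv(4->4) 27*4*4+4, norms 2*(2*4)
  # bottleneck: conv(4->8) 27*4*8+8, conv(8->8) 27*8*8+8, norms 2*(2*8)
  # decoder: up conv(8->4) 27*8*4+4, conv(8->4) 27*8*4+4, conv(4->4) 27*4*4+4,
  #          norms 3*(2*4)
  # head: 4*6+6
  hand <- (27 * 4 + 4) + (27 * 16 + 4) + 16 +
    (27 * 32 + 8) + (27 * 64 + 8) + 32 +
    (27 * 32 + 4) + (27 * 32 + 4) + (27 * 16 + 4) + 24 +
    (4 * 6 + 6)
  expect_equal(unet_n_params(cfg), hand)
  # and the formula matches the actual weight tensors
  set.seed(1)
  w <- cervimetry:::unet_init_weights(cfg)
  expect_equal(sum(lengths(w)), hand)
})

test_that("preprocessing maps onto the grid and back within a voxel", {
  ph <- straight_phantom()
  img <- rendered_phantom()$image

  pp <- preprocess(img, 64)
  expect_equal(dim(pp$image$voxels), c(64, 64, 64))
  expect_true(all(pp$image$voxels >= 0 & pp$image$voxels <= 1))

  # grid-shaped input at its own size keeps its geometry
  cube <- image_volume(array(runif(32^3), c(32, 32, 32)),
                       spacing = c(1, 1, 1))
  pp2 <- preprocess(cube, 32)
  expect_equal(pp2$image$affine, cube$affine, tolerance = 1e-10)

  # anisotropic input: label round-trip through the grid moves boundaries
  # by at most about a voxel
  lab_grid <- cervimetry:::labels_to_grid(ph$labels, pp$meta)
  back <- cervimetry:::labels_from_grid(lab_grid, pp$meta)
  expect_equal(dim(back$voxels), dim(ph$labels$voxels))
  expect_gt(dice_score(ph$labels, back, 1), 0.9)
})

test_that("small padded inputs are centred", {
  small <- image_volume(array(1, c(16, 16, 16)), spacing = c(1, 1, 1))
  pp <- preprocess(small, 32)
  filled <- which(pp$image$voxels > 0, arr.ind = TRUE)
  centre <- colMeans(filled)
  expect_true(all(abs(centre - 16.5) < 1.5))
})

test_that("a short training run learns and is seed-deterministic", {
  pairs <- lapply(1:2, function(i) {
    ph <- straight_phantom()
    list(image = render_intensity(ph$labels, intensity_model(seed = 20 + i)),
         labels = ph$labels)
  })
  cfg <- unet_config(depth = 2, channels = c(3, 6), grid = 24, iterations = 60,
                     seed = 5)
  aug <- augmentation_config(0.1, 0.1, 15)
  m1 <- train_segmentation(pairs, cfg, aug)
  expect_lt(mean(tail(m1$loss_history$loss, 10)),
            mean(head(m1$loss_history$loss, 10)))

  m2 <- train_segmentation(pairs, cfg, aug)
  expect_identical(m1$loss_history, m2$loss_history)

  # label codes outside the class range are rejected
  bad <- pairs
  bad[[1]]$labels$voxels[1] <- 5L
  cfg2 <- unet_config(depth = 2, channels = c(3, 6), grid = 24, iterations = 5,
                      num_classes = 4)
  expect_error(train_segmentation(bad, cfg2, aug), "num_classes")
  expect_error(train_segmentation(pairs[1], cfg, aug), "at least 2")
})

test_that("prediction returns a valid label volume and is deterministic", {
  pairs <- lapply(1:2, function(i) {
    ph <- straight_phantom()
    list(image = render_intensity(ph$labels, intensity_model(seed = 30 + i)),
         labels = ph$labels)
  })
  cfg <- unet_config(depth = 2, channels = c(3, 6), grid = 24, iterations = 40,
                     seed = 6)
  m <- train_segmentation(pairs, cfg, augmentation_config(0, 0, 0))

  p1 <- predict_segmentation(m, pairs[[1]]$image)
  p2 <- predict_segmentation(m, pairs[[1]]$image)
  expect_identical(p1$voxels, p2$voxels)
  expect_identical(dim(p1$voxels), dim(pairs[[1]]$image$voxels))
  expect_true(all(p1$voxels %in% 0:5))

  # an all-zero image still yields a valid label map
  zero <- image_volume(array(0, dim(pairs[[1]]$image$voxels)),
                       affine = pairs[[1]]$image$affine)
  pz <- predict_segmentation(m, zero)
  expect_true(all(pz$voxels %in% 0:5))
})

test_that("histogram matching reproduces the reference distribution", {
  set.seed(8)
  src <- image_volume(array(rnorm(16^3, 5, 2), c(16, 16, 16)))
  ref <- image_volume(array(rexp(16^3), c(16, 16, 16)))
  matched <- histogram_match(src, ref)
  qs <- quantile(matched$voxels, c(0.1, 0.5, 0.9))
  qr <- quantile(ref$voxels, c(0.1, 0.5, 0.9))
  expect_equal(unname(qs), unname(qr), tolerance = 0.05)
  # matching preserves intensity ordering
  ord <- order(src$voxels)
  expect_true(!is.unsorted(matched$voxels[ord]))
})
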