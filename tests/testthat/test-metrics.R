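make_mask_volume <- function(fill_fun, dims = c(20, 20, 20)) {
  vox <- array(0L, dims)
  fill_fun(vox)
}

test_that("dice obeys its identities and symmetry", {
  a <- array(0L, c(20, 20, 20))
  a[1:10, 1:10, 1] <- 1L               # 100 voxels
  b <- array(0L, c(20, 20, 20))
  b[6:15, 1:10, 1] <- 1L               # shifted: overlap 50
  va <- label_volume(a)
  vb <- label_volume(b)

  expect_equal(dice_score(va, va, 1), 1)
  expect_equal(dice_score(va, vb, 1), 0.5)
  expect_equal(dice_score(va, vb, 1), dice_score(vb, va, 1))
  # disjoint equal-size masks
  c_ <- array(0L, c(20, 20, 20))
  c_[1:10, 1:10, 5] <- 1L
  expect_equal(dice_score(va, label_volume(c_), 1), 0)
  # both empty -> 1 by convention
  expect_equal(dice_score(va, vb, 4), 1)
  expect_error(dice_score(va, label_volume(array(0L, c(10, 10, 10))), 1),
               "same grid")
})

test_that("volume differences are referenced to the first argument", {
  a <- array(0L, c(20, 20, 20)); a[1:10, 1:10, 1:10] <- 1L  # 1000 mm^3
  b <- array(0L, c(20, 20, 20)); b[1:10, 1:10, 1:9] <- 1L   # 900 mm^3
  va <- label_volume(a); vb <- label_volume(b)
  vd <- volume_difference(va, vb, 1)
  expect_equal(vd$absolute_mm3, 100)
  expect_equal(vd$relative_pct, 10)
  expect_equal(volume_difference(va, va, 1),
               list(absolute_mm3 = 0, relative_pct = 0))
  expect_equal(volume_difference(va, vb, 4),
               list(absolute_mm3 = 0, relative_pct = 0))
  expect_warning(vd0 <- volume_difference(vb, va, 5), NA)
  # zero reference with non-zero prediction is flagged
  b[1, 1, 1] <- 5L
  expect_warning(out <- volume_difference(va, label_volume(b), 5), "undefined")
  expect_true(is.na(out$relative_pct))
})

test_that("ICC(2,1) is exact for perfect agreement and degenerate data", {
  m <- cbind(1:10, 1:10)
  expect_equal(icc(m), 1)
  expect_warning(v <- icc(matrix(3, 5, 3)), "zero variance")
  expect_equal(v, 1)
  expect_error(icc(matrix(1:10, ncol = 1)), "2 raters")
  expect_error(icc(matrix(1:4, 2, 2)), "3 cases")
})

test_that("ICC recovers the variance-ratio ground truth in simulation", {
  n <- 200
  k <- 2
  set.seed(404)
  # no case effect: expect ICC near zero
  noise_only <- matrix(rnorm(n * k), n, k)
  expect_lt(abs(icc(noise_only)), 0.15)

  # case SD 4, noise SD 1 -> ICC = 16/17
  reps <- sapply(1:20, function(r) {
    case <- rnorm(n, sd = 4)
    icc(matrix(case, n, k) + matrix(rnorm(n * k), n, k))
  })
  expect_equal(mean(reps), 16 / 17, tolerance = 0.04 / (16 / 17))
  # Monte-Carlo spread is small
  expect_lt(sd(reps), 0.02)
})

test_that("agreement reports summarise per-label overlap", {
  ph <- straight_phantom()
  rep0 <- agreement_report(ph$labels, ph$labels)
  expect_true(all(rep0$dice == 1))
  expect_true(all(rep0$rel_volume_diff_pct == 0))
  expect_setequal(rep0$label, c(1, 2, 3))
})
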