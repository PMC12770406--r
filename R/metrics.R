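#' Dice overlap for one label
#'
#' `2|A intersect B| / (|A| + |B|)` between the masks of `label` in two
#' volumes on the same grid. Defined as 1 when both masks are empty.
#'
#' @param a,b [label_volume()] objects on identical grids.
#' @param label Label code to compare.
#' @return Dice fraction in `[0, 1]`.
#' @export
dice_score <- function(a, b, label) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!same_grid(a, b)) stop("volumes are not on the same grid", call. = FALSE)
  ma <- a$voxels == label
  mb <- b$voxels == label
  na <- sum(ma)
  nb <- sum(mb)
  if (na + nb == 0) return(1.0)
  2 * sum(ma & mb) / (na + nb)
}

#' Absolute and relative volume difference for one label
#'
#' The absolute difference `|V_a - V_b|` in cubic millimetres and the
#' relative difference `100 |V_a - V_b| / V_a` in percent, referenced to
#' the first argument (the ground-truth/refined labels).
#'
#' @inheritParams dice_score
#' @return List with `absolute_mm3` and `relative_pct` (NA with a warning
#'   when the reference volume is zero but the other is not; 0 when both
#'   are zero).
#' @export
volume_difference <- function(a, b, label) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!same_grid(a, b)) stop("volumes are not on the same grid", call. = FALSE)
  va <- sum(a$voxels == label) * voxel_volume_mm3(a)
  vb <- sum(b$voxels == label) * voxel_volume_mm3(b)
  absolute <- abs(va - vb)
  relative <- if (va == 0 && vb == 0) {
    0
  } else if (va == 0) {
    warning("reference volume is zero; relative difference undefined")
    NA_real_
  } else {
    100 * absolute / va
  }
  list(absolute_mm3 = absolute, relative_pct = relative)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation from the standard mean-squares decomposition: with `n`
#' cases (rows) and `k` raters (columns),
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param measurements Numeric matrix, cases in rows, raters/methods in
#'   columns; no missing cells.
#' @return ICC estimate. Degenerate all-equal data returns 1 with a
#'   warning.
#' @export
icc <- function(measurements) {
  m <- as.matrix(measurements)
  if (!is.numeric(m) || anyNA(m)) {
    stop("measurements must be a complete numeric matrix", call. = FALSE)
  }
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2) stop("need at least 2 raters (columns)", call. = FALSE)
  if (n < 3) stop("need at least 3 cases (rows)", call. = FALSE)

  grand <- mean(m)
  if (all(abs(m - grand) < 1e-12)) {
    warning("zero variance in measurements; ICC defined as 1")
    return(1.0)
  }
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  resid <- m - outer(row_means, rep(1, k)) -
    outer(rep(1, n), col_means) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Segmentation agreement report between two label volumes
#'
#' Per-label Dice and absolute/relative volume differences of `pred`
#' against the reference `ref`, for every non-background label present in
#' either volume.
#'
#' @param ref Reference [label_volume()] (ground truth / refined labels).
#' @param pred Predicted [label_volume()] on the same grid.
#' @return An object of class `agreement_report`: a data frame with one
#'   row per label.
#' @export
agreement_report <- function(ref, pred) {
  stopifnot(inherits(ref, "label_volume"), inherits(pred, "label_volume"))
  if (!same_grid(ref, pred)) stop("volumes are not on the same grid", call. = FALSE)
  labs <- sort(unique(c(unique(as.integer(ref$voxels)),
                        unique(as.integer(pred$voxels)))))
  labs <- setdiff(labs, 0L)
  rows <- lapply(labs, function(lab) {
    vd <- suppressWarnings(volume_difference(ref, pred, lab))
    data.frame(
      label = lab,
      name = names(cervix_labels)[match(lab, cervix_labels)],
      dice = dice_score(ref, pred, lab),
      abs_volume_diff_mm3 = vd$absolute_mm3,
      rel_volume_diff_pct = vd$relative_pct
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_report", "data.frame")
  out
}
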