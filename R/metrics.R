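#' Threshold a volume into a brain mask
#'
#' For skull-stripped volumes the brain field is simply the region of
#' positive intensity, so the default threshold is 0.
#'
#' @param vol An [image_volume] (or array).
#' @param threshold Intensities strictly above this become 1.
#' @return An [image_volume] of 0/1 values.
#' @export
brain_mask_from_volume <- function(vol, threshold = 0) {
  arr <- as_vox_array(vol)
  image_volume(array(as.numeric(arr > threshold), dim(arr)))
}

#' Dice similarity coefficient of two binary masks
#'
#' `Dice(A, B) = 2 |A and B| / (|A| + |B|)`, the volume-overlap score of
#' the warped and fixed brain masks. Two empty masks score 1 by
#' convention (the 0/0 limit of perfect agreement); empty versus
#' non-empty scores 0.
#'
#' @param a,b 0/1 [image_volume]s (or arrays) of identical shape.
#' @return A scalar in \[0, 1\].
#' @export
dice_score <- function(a, b) {
  a <- as_vox_array(a); b <- as_vox_array(b)
  if (!all(dim(a) == dim(b)))
    stop("mask shapes differ", call. = FALSE)
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("masks must be binary (0/1)", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Structural similarity index of two volumes
#'
#' Computes `SSIM = (2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#' ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))` with
#' `C1 = (k1 L)^2`, `C2 = (k2 L)^2`, `L = data_range`. By default the
#' statistics are taken over sliding cubic windows (uniform weights,
#' full windows only) and the per-window values averaged; with
#' `global = TRUE` the whole volume is treated as a single window, the
#' literal one-window form of the formula. Moments use the biased
#' (divide by n) normalization.
#'
#' @param x,y [image_volume]s (or arrays) of identical shape.
#' @param k1,k2 Stabilizer coefficients (canonical 0.01 and 0.03).
#' @param data_range Intensity range `L` (1 for \[0,1\]-normalized
#'   volumes).
#' @param window Odd window edge length (default 7).
#' @param global If `TRUE`, compute the single-window global form.
#' @return A scalar in \[-1, 1\].
#' @export
ssim_score <- function(x, y, k1 = 0.01, k2 = 0.03, data_range = 1,
                       window = 7L, global = FALSE) {
  x <- as_vox_array(x); y <- as_vox_array(y)
  if (!all(dim(x) == dim(y)))
    stop("volume shapes differ", call. = FALSE)
  C1 <- (k1 * data_range)^2
  C2 <- (k2 * data_range)^2
  if (global) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  window <- as.integer(window)
  d <- dim(x)
  if (window %% 2L == 0L || window < 3L || any(d < window))
    stop("`window` must be odd, >= 3 and no larger than the volume", call. = FALSE)
  n <- as.numeric(window)^3
  xs <- as.numeric(x); ys <- as.numeric(y)
  mx <- boxsum3(xs, d, window) / n
  my <- boxsum3(ys, d, window) / n
  vx <- boxsum3(xs * xs, d, window) / n - mx^2
  vy <- boxsum3(ys * ys, d, window) / n - my^2
  cxy <- boxsum3(xs * ys, d, window) / n - mx * my
  ssim_map <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  # zero-padded box sums are exact only where the window fits entirely
  # inside the volume; average over those interior centres
  r <- window %/% 2L
  keep <- array(FALSE, d)
  keep[(r + 1):(d[1] - r), (r + 1):(d[2] - r), (r + 1):(d[3] - r)] <- TRUE
  mean(array(ssim_map, d)[keep])
}

#' Mean endpoint error between two displacement fields
#'
#' Mean Euclidean distance, over masked voxels, between predicted and
#' ground-truth displacement vectors (voxel units). Only synthetic pairs
#' carry a ground-truth field, so this is a phantom-only metric.
#'
#' @param pred,truth [deformation_field]s of identical shape.
#' @param mask Optional 0/1 [image_volume] (or array) restricting the
#'   average; default all voxels.
#' @return Mean endpoint error in voxels.
#' @export
mean_endpoint_error <- function(pred, truth, mask = NULL) {
  stopifnot(inherits(pred, "deformation_field"),
            inherits(truth, "deformation_field"))
  if (!all(dim(pred) == dim(truth)))
    stop("field shapes differ", call. = FALSE)
  diff <- field_matrix(pred) - field_matrix(truth)
  epe <- sqrt(rowSums(diff^2))
  if (!is.null(mask)) {
    m <- as.numeric(as_vox_array(mask)) > 0
    if (!any(m)) stop("mask is empty", call. = FALSE)
    epe <- epe[m]
  }
  mean(epe)
}

#' Evaluate one registration
#'
#' Computes the standard report for a registered pair: Dice of the
#' warped moving mask against the fixed mask, SSIM of the warped volume
#' against the fixed volume, the two loss components, and (when the pair
#' carries a ground-truth field) the mean endpoint error of the
#' predicted field.
#'
#' @param pair A `registration_pair`.
#' @param warped The warped moving [image_volume].
#' @param field The predicted [deformation_field].
#' @param cfg A [loss_config] for the loss components.
#' @return A one-row data frame: `dice`, `ssim`, `sim_loss`,
#'   `smooth_loss`, `epe_mean` (`NA` without ground truth).
#' @export
evaluate_pair <- function(pair, warped, field, cfg = loss_config()) {
  warped_mask <- warp_volume(pair$moving_mask, field, mode = "nearest")
  loss <- total_loss(pair$fixed, warped, field, cfg)
  epe <- if (!is.null(pair$true_field))
    mean_endpoint_error(field, pair$true_field, mask = pair$fixed_mask)
  else NA_real_
  data.frame(dice = dice_score(warped_mask, pair$fixed_mask),
             ssim = ssim_score(warped, pair$fixed),
             sim_loss = loss$sim, smooth_loss = loss$smooth,
             epe_mean = epe)
}
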