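#' Parameters of the synthetic brain phantom
#'
#' The phantom emulates a skull-stripped brain MR volume: zero
#' background, a smooth ellipsoidal "brain" whose intensity falls off
#' radially, a configurable number of internal ellipsoidal structures of
#' distinct intensity, and one low-intensity spherical lesion. It stands
#' in for glioma scan pairs so the full registration pipeline can be
#' exercised without any imaging data.
#'
#' @param shape Integer length-3 grid size, every axis at least 16.
#' @param n_structures Number of internal ellipsoidal structures.
#' @param lesion_radius_frac Lesion radius as a fraction of the smallest
#'   grid dimension, in (0, 0.3]; 0 disables the lesion.
#' @param texture_amp Amplitude (intensity sd) of the smooth parenchymal
#'   texture baked into the anatomy. Real MR tissue is textured
#'   everywhere, which is what makes a dense deformation identifiable
#'   from intensities; 0 gives a texture-free (piecewise-smooth) phantom.
#' @param noise_sd Standard deviation of additive Gaussian acquisition
#'   noise applied inside the brain mask (intensity units, < 0.5);
#'   unlike the texture, noise is drawn independently per image.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(shape = c(32, 32, 32), n_structures = 3L,
                           lesion_radius_frac = 0.12, texture_amp = 0.1,
                           noise_sd = 0.02, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("`shape` must be 3 integers, each >= 16", call. = FALSE)
  if (noise_sd < 0 || noise_sd >= 0.5)
    stop("`noise_sd` must be in [0, 0.5)", call. = FALSE)
  if (lesion_radius_frac < 0 || lesion_radius_frac > 0.3)
    stop("`lesion_radius_frac` must be in [0, 0.3]", call. = FALSE)
  if (n_structures < 0) stop("`n_structures` must be >= 0", call. = FALSE)
  if (texture_amp < 0 || texture_amp > 0.3)
    stop("`texture_amp` must be in [0, 0.3]", call. = FALSE)
  structure(list(shape = shape, n_structures = as.integer(n_structures),
                 lesion_radius_frac = lesion_radius_frac,
                 texture_amp = texture_amp,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_params")
}

#' Generate a skull-stripped brain-like phantom
#'
#' @param params A [phantom_params].
#' @return A list with `volume` (an [image_volume], background exactly 0,
#'   brain intensities in \[0.2, 1\]) and `mask` (an [image_volume] of
#'   0/1 values equal to `volume > 0`).
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  shape <- params$shape
  with_seed(params$seed, {
    g <- identity_grid(shape)
    centre <- (shape - 1) / 2
    semi <- 0.38 * shape * runif(3, 0.92, 1.08)
    if (params$lesion_radius_frac * min(shape) >= min(semi))
      stop("lesion radius exceeds the brain semi-axes", call. = FALSE)
    # normalized squared elliptic radius; <= 1 inside the brain
    r2 <- ((g[, , , 1] - centre[1]) / semi[1])^2 +
          ((g[, , , 2] - centre[2]) / semi[2])^2 +
          ((g[, , , 3] - centre[3]) / semi[3])^2
    inside <- r2 <= 1
    # smooth radial profile 0.85 at the core to 0.30 at the rim
    vol <- ifelse(inside, 0.85 - 0.55 * r2, 0)
    if (params$n_structures > 0L) {
      for (k in seq_len(params$n_structures)) {
        sc <- centre + runif(3, -0.45, 0.45) * semi
        ss <- runif(3, 0.08, 0.16) * shape
        sr2 <- ((g[, , , 1] - sc[1]) / ss[1])^2 +
               ((g[, , , 2] - sc[2]) / ss[2])^2 +
               ((g[, , , 3] - sc[3]) / ss[3])^2
        level <- 0.3 + 0.6 * (k - 0.5) / params$n_structures
        vol[inside & sr2 <= 1] <- level
      }
    }
    if (params$lesion_radius_frac > 0) {
      lr <- params$lesion_radius_frac * min(shape)
      lc <- centre + runif(3, -0.35, 0.35) * semi
      lr2 <- (g[, , , 1] - lc[1])^2 + (g[, , , 2] - lc[2])^2 +
             (g[, , , 3] - lc[3])^2
      vol[inside & lr2 <= lr^2] <- 0.22
    }
    if (params$texture_amp > 0) {
      # smooth anatomical texture: part of the tissue, so a deformed
      # phantom carries correspondence information everywhere
      tex <- gauss_smooth3(array(rnorm(prod(shape)), shape), 2)
      tex <- tex / sd(tex)
      vol[inside] <- pmin(pmax(vol[inside] + params$texture_amp * tex[inside],
                               0.2), 1)
    }
    if (params$noise_sd > 0) {
      noise <- array(rnorm(prod(shape), sd = params$noise_sd), shape)
      # clip to (0, 1] so the mask stays exactly (intensity > 0)
      vol[inside] <- pmin(pmax(vol[inside] + noise[inside], 0.02), 1)
    }
    mask <- array(as.numeric(inside), shape)
    vol <- array(vol, shape)
    list(volume = image_volume(vol), mask = image_volume(mask))
  })
}

#' Sample a smooth random displacement field
#'
#' Each component is white Gaussian noise convolved with an isotropic
#' Gaussian of standard deviation `smooth_sigma`, forced to zero on a
#' 2-voxel boundary shell (so no sample ever maps outside the grid), and
#' rescaled so the maximum displacement magnitude equals `amplitude`.
#'
#' @param shape Integer length-3 grid size.
#' @param amplitude Maximum displacement magnitude in voxels (>= 0).
#' @param smooth_sigma Gaussian smoothing standard deviation in voxels
#'   (> 0); larger values give smoother fields.
#' @param seed Integer seed.
#' @return A [deformation_field].
#' @export
sample_smooth_field <- function(shape, amplitude, smooth_sigma, seed = 1L) {
  shape <- as.integer(shape)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (smooth_sigma <= 0) stop("`smooth_sigma` must be > 0", call. = FALSE)
  s <- array(0, c(shape, 3L))
  if (amplitude > 0) {
    with_seed(seed, {
      for (c in 1:3)
        s[, , , c] <- gauss_smooth3(array(rnorm(prod(shape)), shape), smooth_sigma)
    })
    # zero 2-voxel margin, then rescale the interior maximum exactly
    margin <- array(1, shape)
    for (ax in 1:3) {
      idx <- rep(list(quote(expr = )), 3L)
      idx[[ax]] <- c(1:2, shape[ax] - 1:0)
      margin <- do.call(`[<-`, c(list(margin), idx, list(0)))
    }
    for (c in 1:3) s[, , , c] <- s[, , , c] * margin
    mag <- sqrt(s[, , , 1]^2 + s[, , , 2]^2 + s[, , , 3]^2)
    mx <- max(mag)
    if (mx > 0) s <- s * (amplitude / mx)
  }
  deformation_field(s)
}

# Separable Gaussian convolution (zero padded) along each axis.
gauss_smooth3 <- function(arr, sigma) {
  d <- dim(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  for (ax in 1:3) {
    m <- matrix(aperm(arr, c(ax, setdiff(1:3, ax))), nrow = d[ax])
    n <- d[ax]
    padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    sm <- matrix(0, n, ncol(m))
    for (i in seq_along(k))
      sm <- sm + k[i] * padded[(i - 1) + seq_len(n), , drop = FALSE]
    out_perm <- array(sm, d[c(ax, setdiff(1:3, ax))])
    arr <- aperm(out_perm, order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

# Fixed-point inversion of a displacement field: find s_inv with
# s_inv(x) = -s(x + s_inv(x)). Accurate for the smooth, modest-amplitude
# fields the sampler produces.
invert_field <- function(field, iters = 10L) {
  d <- dim(field)[1:3]
  fm <- field_matrix(field)
  inv <- -fm
  for (i in seq_len(iters)) {
    inv <- -vapply(1:3, function(c)
      warp_fw(as.numeric(array(fm[, c], d)), d, inv, FALSE),
      numeric(nrow(fm)))
  }
  field_from_matrix(inv, d)
}

#' Build a synthetic registration pair with known ground truth
#'
#' Generates a fixed phantom and a moving image related to it by a known
#' smooth deformation. The stored `true_field` registers moving onto
#' fixed: warping `moving` by `true_field` reproduces `fixed` up to
#' interpolation error and noise. The moving image is produced by
#' resampling the noiseless fixed phantom through the (fixed-point)
#' inverse of that field; each image then receives its own independent
#' noise realization.
#'
#' @param params A [phantom_params].
#' @param amplitude Maximum true displacement magnitude in voxels.
#' @param smooth_sigma Smoothness of the true field, in voxels.
#' @return A `registration_pair` list: `fixed`, `moving`, `fixed_mask`,
#'   `moving_mask` ([image_volume]s) and `true_field`
#'   (a [deformation_field]).
#' @export
make_registration_pair <- function(params = phantom_params(), amplitude = 2,
                                   smooth_sigma = 6) {
  stopifnot(inherits(params, "phantom_params"))
  clean_params <- params
  clean_params$noise_sd <- 0
  ph <- generate_phantom(clean_params)
  shape <- params$shape
  s <- sample_smooth_field(shape, amplitude, smooth_sigma,
                           seed = params$seed + 1000L)
  s_inv <- invert_field(s)
  moving_clean <- warp_volume(ph$volume, s_inv)
  moving_mask <- warp_volume(ph$mask, s_inv, mode = "nearest")
  fixed <- add_masked_noise(ph$volume, ph$mask, params$noise_sd,
                            params$seed + 2000L)
  moving <- add_masked_noise(moving_clean, moving_mask, params$noise_sd,
                             params$seed + 3000L)
  structure(list(fixed = fixed, moving = moving,
                 fixed_mask = ph$mask, moving_mask = moving_mask,
                 true_field = s),
            class = "registration_pair")
}

add_masked_noise <- function(vol, mask, noise_sd, seed) {
  if (noise_sd <= 0) return(vol)
  d <- dim(vol$voxels)
  with_seed(seed, {
    noise <- array(rnorm(prod(d), sd = noise_sd), d)
    out <- vol$voxels + noise * (mask$voxels > 0)
    out[mask$voxels > 0] <- pmin(pmax(out[mask$voxels > 0], 0.02), 1)
    image_volume(out, spacing = vol$spacing, origin = vol$origin)
  })
}

#' Write a registration pair to a directory as NIfTI files
#'
#' Emits `fixed.nii.gz`, `moving.nii.gz`, `fixed_mask.nii.gz`,
#' `moving_mask.nii.gz` and, when present, `true_field.nii.gz` (4-D,
#' last axis the displacement components in voxel units).
#'
#' @param pair A `registration_pair`.
#' @param dir Destination directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_registration_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "registration_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_volume(pair$fixed, file.path(dir, "fixed.nii.gz"))
  save_volume(pair$moving, file.path(dir, "moving.nii.gz"))
  save_volume(pair$fixed_mask, file.path(dir, "fixed_mask.nii.gz"))
  save_volume(pair$moving_mask, file.path(dir, "moving_mask.nii.gz"))
  if (!is.null(pair$true_field))
    save_field(pair$true_field, file.path(dir, "true_field.nii.gz"))
  invisible(dir)
}

#' Load a registration pair written by [save_registration_pair()]
#'
#' @param dir Directory containing the pair.
#' @return A `registration_pair`; `true_field` is `NULL` when absent
#'   (as for real data).
#' @export
load_registration_pair <- function(dir) {
  tf <- file.path(dir, "true_field.nii.gz")
  structure(list(
    fixed = load_volume(file.path(dir, "fixed.nii.gz")),
    moving = load_volume(file.path(dir, "moving.nii.gz")),
    fixed_mask = load_volume(file.path(dir, "fixed_mask.nii.gz")),
    moving_mask = load_volume(file.path(dir, "moving_mask.nii.gz")),
    true_field = if (file.exists(tf)) load_field(tf) else NULL
  ), class = "registration_pair")
}
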