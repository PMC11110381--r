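#' Loss configuration
#'
#' @param lambda_reg Nonnegative weight of the smoothness penalty
#'   (default 1, the setting that registers best in practice).
#' @param ncc_window Odd window edge length for the local NCC (default 9,
#'   i.e. 9 x 9 x 9 neighbourhoods).
#' @param eps Stabilizer added to the NCC variance product; keeps flat
#'   (background) windows from dividing by ~0.
#' @return A `loss_config` list.
#' @export
loss_config <- function(lambda_reg = 1, ncc_window = 9L, eps = 1e-5) {
  ncc_window <- as.integer(ncc_window)
  if (ncc_window < 3L || ncc_window %% 2L == 0L)
    stop("`ncc_window` must be odd and >= 3", call. = FALSE)
  if (lambda_reg < 0) stop("`lambda_reg` must be >= 0", call. = FALSE)
  if (eps <= 0) stop("`eps` must be > 0", call. = FALSE)
  structure(list(lambda_reg = lambda_reg, ncc_window = ncc_window, eps = eps),
            class = "loss_config")
}

as_vox_array <- function(x) {
  if (inherits(x, "image_volume")) x$voxels else x
}

# Windowed moments shared by the NCC value and its gradient. Sums are
# zero-padded box sums; means divide by the number of in-bounds voxels in
# each window (windows shrink at the borders), so every window's moments
# are its true local statistics.
ncc_parts <- function(a, b, window, eps) {
  d <- dim(a)
  n <- boxsum3(rep(1, prod(d)), d, window)
  av <- as.numeric(a); bv <- as.numeric(b)
  A <- boxsum3(av, d, window)
  B <- boxsum3(bv, d, window)
  AB <- boxsum3(av * bv, d, window)
  AA <- boxsum3(av * av, d, window)
  BB <- boxsum3(bv * bv, d, window)
  cross <- AB - A * B / n
  var_a <- pmax(AA - A * A / n, 0)
  var_b <- pmax(BB - B * B / n, 0)
  den <- var_a * var_b + eps
  list(A = A, B = B, cross = cross, var_a = var_a, var_b = var_b,
       den = den, cc = cross * cross / den, n = n, d = d)
}

#' Local normalized cross-correlation similarity
#'
#' The squared local cross-correlation
#' `CC = (sum (a - abar)(b - bbar))^2 / (sum (a - abar)^2 sum (b - bbar)^2 + eps)`
#' computed over a centred cubic window at every voxel and averaged over
#' the volume. Window sums come from box filters; at the volume borders
#' the windows shrink to their in-bounds part, whose voxel count
#' normalizes the local means, so every window uses its true local
#' statistics and the score is invariant to affine intensity maps
#' everywhere. Values lie in \[0, 1\]; 1 means the images are locally
#' affinely related everywhere (flat windows score 0 through `eps`).
#' The similarity term of the registration loss is its negative.
#'
#' @param a,b Two [image_volume]s (or arrays) of identical shape.
#' @param window Odd window edge length (default 9).
#' @param eps Variance-product stabilizer.
#' @return A scalar in \[0, 1\].
#' @export
local_ncc <- function(a, b, window = 9L, eps = 1e-5) {
  a <- as_vox_array(a); b <- as_vox_array(b)
  if (!all(dim(a) == dim(b)))
    stop("`a` and `b` must have the same shape", call. = FALSE)
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L)
    stop("`window` must be odd and >= 3", call. = FALSE)
  mean(ncc_parts(a, b, window, eps)$cc)
}

# Gradient of local_ncc(a, b) with respect to b; used by the training
# engine (the loss gradient is its negative). Derived by differentiating
# the windowed moments: with P = 2 cross / den and Q = 2 cc var_a / den,
#   d ncc / d b_j = (1/N) [ a_j box(P) - box(P A / n)
#                          - b_j box(Q) + box(Q B / n) ].
local_ncc_grad <- function(a, b, window = 9L, eps = 1e-5) {
  a <- as_vox_array(a); b <- as_vox_array(b)
  p <- ncc_parts(a, b, window, eps)
  N <- prod(p$d)
  P <- 2 * p$cross / p$den
  Q <- 2 * p$cc * p$var_a / p$den
  g <- (as.numeric(a) * boxsum3(P, p$d, window) -
          boxsum3(P * p$A / p$n, p$d, window) -
          as.numeric(b) * boxsum3(Q, p$d, window) +
          boxsum3(Q * p$B / p$n, p$d, window)) / N
  array(g, p$d)
}

#' Diffusion regularizer of a displacement field
#'
#' Approximates the smoothness penalty `sum ||grad s||^2` with forward
#' differences between neighbouring voxels: for each axis the squared
#' differences of all three displacement components are summed per
#' position and averaged over positions, and the three axis means are
#' averaged. The mean (rather than sum) reduction makes the penalty — and
#' therefore the weight `lambda` — independent of grid resolution.
#'
#' @param field A [deformation_field].
#' @return A nonnegative scalar; 0 exactly when the field is constant.
#' @export
diffusion_regularizer <- function(field) {
  stopifnot(inherits(field, "deformation_field"))
  s <- field$displacements
  d <- dim(s)[1:3]
  total <- 0
  for (ax in 1:3) {
    if (d[ax] < 2L) next
    idx_hi <- idx_lo <- rep(list(quote(expr = )), 4L)
    idx_hi[[ax]] <- 2:d[ax]
    idx_lo[[ax]] <- 1:(d[ax] - 1L)
    df <- do.call(`[`, c(list(s), idx_hi)) - do.call(`[`, c(list(s), idx_lo))
    npos <- prod(d) / d[ax] * (d[ax] - 1L)
    total <- total + sum(df * df) / npos
  }
  total / 3
}

# Gradient of diffusion_regularizer with respect to the field, as a 4-D
# array matching the displacements.
diffusion_grad <- function(field) {
  s <- field$displacements
  d <- dim(s)[1:3]
  g <- array(0, dim(s))
  for (ax in 1:3) {
    if (d[ax] < 2L) next
    idx_hi <- idx_lo <- rep(list(quote(expr = )), 4L)
    idx_hi[[ax]] <- 2:d[ax]
    idx_lo[[ax]] <- 1:(d[ax] - 1L)
    df <- do.call(`[`, c(list(s), idx_hi)) - do.call(`[`, c(list(s), idx_lo))
    npos <- prod(d) / d[ax] * (d[ax] - 1L)
    w <- 2 / (3 * npos)
    gh <- do.call(`[`, c(list(g), idx_hi))
    g <- assign_slice(g, idx_hi, gh + w * df)
    gl <- do.call(`[`, c(list(g), idx_lo))  # re-read: hi and lo overlap
    g <- assign_slice(g, idx_lo, gl - w * df)
  }
  g
}

assign_slice <- function(arr, idx, value) {
  do.call(`[<-`, c(list(arr), idx, list(value)))
}

#' Total unsupervised registration loss
#'
#' `Loss = L_sim + lambda * L_smooth` where `L_sim` is the negative local
#' NCC between the fixed and the warped moving image and `L_smooth` is
#' the diffusion regularizer of the predicted field.
#'
#' @param fixed,warped [image_volume]s of identical shape.
#' @param field The predicted [deformation_field].
#' @param cfg A [loss_config].
#' @return A list with elements `total`, `sim` (`= -ncc`), `smooth` and
#'   `ncc`.
#' @export
total_loss <- function(fixed, warped, field, cfg = loss_config()) {
  ncc <- local_ncc(fixed, warped, window = cfg$ncc_window, eps = cfg$eps)
  smooth <- diffusion_regularizer(field)
  list(total = -ncc + cfg$lambda_reg * smooth,
       sim = -ncc, smooth = smooth, ncc = ncc)
}
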