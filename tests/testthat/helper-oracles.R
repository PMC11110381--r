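# Independent brute-force reference implementations used to cross-check
# the package's vectorized/compiled kernels, plus small fixture builders.
# These deliberately use naive per-voxel loops and share no code with the
# implementation under test.

rand_vol <- function(shape, seed) {
  set.seed(seed)
  array(runif(prod(shape)), shape)
}

rand_field <- function(shape, amplitude, seed) {
  set.seed(seed)
  deformation_field(array(runif(prod(shape) * 3, -amplitude, amplitude),
                          c(shape, 3L)))
}

# Per-voxel trilinear (or nearest) warp with border clamping.
ref_warp <- function(arr, field, nearest = FALSE) {
  d <- dim(arr)
  disp <- field$displacements
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    p <- c(i - 1 + disp[i, j, k, 1], j - 1 + disp[i, j, k, 2],
           k - 1 + disp[i, j, k, 3])
    p <- pmin(pmax(p, 0), d - 1)
    if (nearest) {
      q <- round(p) + 1
      out[i, j, k] <- arr[q[1], q[2], q[3]]
      next
    }
    f0 <- pmax(pmin(floor(p), d - 2), 0)
    fr <- p - f0
    acc <- 0
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      w <- (if (cx) fr[1] else 1 - fr[1]) *
           (if (cy) fr[2] else 1 - fr[2]) *
           (if (cz) fr[3] else 1 - fr[3])
      acc <- acc + w * arr[min(f0[1] + cx, d[1] - 1) + 1,
                           min(f0[2] + cy, d[2] - 1) + 1,
                           min(f0[3] + cz, d[3] - 1) + 1]
    }
    out[i, j, k] <- acc
  }
  out
}

# Windowed squared cross-correlation via explicit window extraction at
# every voxel; windows are clipped at the volume borders and moments
# divide by the actual number of voxels in each window.
ref_local_ncc <- function(a, b, window, eps = 1e-5) {
  d <- dim(a)
  r <- window %/% 2
  cc <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    xs <- max(1, i - r):min(d[1], i + r)
    ys <- max(1, j - r):min(d[2], j + r)
    zs <- max(1, k - r):min(d[3], k + r)
    wa <- a[xs, ys, zs]
    wb <- b[xs, ys, zs]
    n <- length(wa)
    A <- sum(wa); B <- sum(wb)
    cross <- sum(wa * wb) - A * B / n
    va <- max(sum(wa * wa) - A^2 / n, 0)
    vb <- max(sum(wb * wb) - B^2 / n, 0)
    cc[i, j, k] <- cross^2 / (va * vb + eps)
  }
  mean(cc)
}

# Diffusion penalty by explicit summation: per axis, mean over forward
# differences of the summed squared component differences; axes averaged.
ref_diffusion <- function(field) {
  s <- field$displacements
  d <- dim(s)[1:3]
  ax_mean <- numeric(3)
  for (ax in 1:3) {
    tot <- 0
    cnt <- 0
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      nb <- c(i, j, k)
      nb[ax] <- nb[ax] + 1
      if (nb[ax] > d[ax]) next
      for (comp in 1:3)
        tot <- tot + (s[nb[1], nb[2], nb[3], comp] - s[i, j, k, comp])^2
      cnt <- cnt + 1
    }
    ax_mean[ax] <- tot / cnt
  }
  mean(ax_mean)
}

# Windowed SSIM by direct evaluation of the formula on every full
# interior window (biased moments), averaged.
ref_ssim <- function(x, y, window, k1 = 0.01, k2 = 0.03, L = 1) {
  d <- dim(x)
  r <- window %/% 2
  C1 <- (k1 * L)^2
  C2 <- (k2 * L)^2
  vals <- c()
  for (k in (r + 1):(d[3] - r)) for (j in (r + 1):(d[2] - r))
    for (i in (r + 1):(d[1] - r)) {
      wx <- x[(i - r):(i + r), (j - r):(j + r), (k - r):(k + r)]
      wy <- y[(i - r):(i + r), (j - r):(j + r), (k - r):(k + r)]
      mx <- mean(wx); my <- mean(wy)
      vx <- mean((wx - mx)^2); vy <- mean((wy - my)^2)
      cxy <- mean((wx - mx) * (wy - my))
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  mean(vals)
}

# Central finite difference of f at x (numeric vector), for gradient checks.
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
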