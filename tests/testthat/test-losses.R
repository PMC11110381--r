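test_that("local NCC is ~1 for self- and affinely-related images", {
  a <- rand_vol(c(32, 32, 32), 1)
  expect_gte(local_ncc(a, a, window = 9), 0.999)
  b <- 2 * a + 0.3
  expect_equal(local_ncc(a, b, window = 9), local_ncc(a, a, window = 9),
               tolerance = 1e-6)
  # contrast inversion is also a local affine map: squared CC is robust to it
  expect_equal(local_ncc(a, 1 - a, window = 9), local_ncc(a, a, window = 9),
               tolerance = 1e-6)
})

test_that("local NCC of independent white noise is small", {
  for (seed in 1:5) {
    a <- rand_vol(c(32, 32, 32), seed)
    b <- rand_vol(c(32, 32, 32), seed + 50)
    expect_lt(local_ncc(a, b, window = 9), 0.2)
  }
})

test_that("local NCC matches the brute-force windowed oracle", {
  for (case in 1:30) {
    set.seed(case)
    d <- c(sample(4:6, 1), sample(4:6, 1), sample(4:6, 1))
    w <- sample(c(3, 5), 1)
    a <- rand_vol(d, case + 100)
    b <- if (case %% 3 == 0) a + array(rnorm(prod(d), sd = 0.1), d)
         else rand_vol(d, case + 200)
    expect_equal(local_ncc(a, b, window = w), ref_local_ncc(a, b, w),
                 tolerance = 1e-9)
  }
})

test_that("NCC gradient matches finite differences", {
  d <- c(6, 6, 6)
  a <- rand_vol(d, 3)
  b <- rand_vol(d, 4)
  analytic <- deformreg:::local_ncc_grad(a, b, window = 3)
  set.seed(5)
  idx <- sample(length(b), 30)
  num <- num_grad(function(v) { bb <- b; bb[idx] <- v; local_ncc(a, bb, window = 3) },
                  b[idx], h = 1e-6)
  expect_equal(as.numeric(analytic)[idx], num, tolerance = 1e-5)
})

test_that("diffusion regularizer: zero for constants, c^2/3 for a ramp, degree-2 homogeneous", {
  const <- deformation_field(array(5.5, c(6, 6, 6, 3)))
  expect_equal(diffusion_regularizer(const), 0)

  # dx = c * i, dy = dz = 0 on a 4^3 grid: mean squared forward difference
  # c^2 along x only, 0 on y/z, so the axis average is c^2 / 3
  cval <- 0.7
  g <- identity_grid(c(4, 4, 4))
  s <- array(0, c(4, 4, 4, 3))
  s[, , , 1] <- cval * g[, , , 1]
  expect_equal(diffusion_regularizer(deformation_field(s)), cval^2 / 3)

  fld <- rand_field(c(6, 6, 6), 2, 11)
  dbl <- deformation_field(2 * fld$displacements)
  expect_equal(diffusion_regularizer(dbl), 4 * diffusion_regularizer(fld),
               tolerance = 1e-12)
})

test_that("diffusion regularizer matches the brute-force oracle and its gradient checks out", {
  for (case in 1:20) {
    d <- c(sample(3:5, 1), sample(3:5, 1), sample(3:5, 1))
    fld <- rand_field(d, 2, case + 40)
    expect_equal(diffusion_regularizer(fld), ref_diffusion(fld),
                 tolerance = 1e-12)
  }
  fld <- rand_field(c(5, 5, 5), 1.5, 77)
  analytic <- deformreg:::diffusion_grad(fld)
  set.seed(7)
  idx <- sample(length(fld$displacements), 30)
  num <- num_grad(function(v) {
    s <- fld$displacements; s[idx] <- v
    diffusion_regularizer(deformation_field(s))
  }, fld$displacements[idx])
  expect_equal(as.numeric(analytic)[idx], num, tolerance = 1e-6)
})

test_that("total loss composes its components", {
  d <- c(16, 16, 16)
  fixed <- image_volume(rand_vol(d, 21))
  warped <- image_volume(rand_vol(d, 22))
  fld <- rand_field(d, 1, 23)

  l0 <- total_loss(fixed, warped, fld, loss_config(lambda_reg = 0))
  expect_equal(l0$total, -local_ncc(fixed, warped, 9))

  l1 <- total_loss(fixed, warped, fld, loss_config(lambda_reg = 1))
  expect_equal(l1$total,
               -local_ncc(fixed, warped, 9) + diffusion_regularizer(fld),
               tolerance = 1e-9)

  # both terms at their optima: identical images, zero field
  zero <- deformation_field(array(0, c(d, 3)))
  opt <- total_loss(fixed, fixed, zero, loss_config(lambda_reg = 1))
  expect_equal(opt$total, -1, tolerance = 1e-3)

  # monotone non-decreasing in lambda when the field is rough
  lams <- c(0, 0.1, 0.2, 0.5, 1)
  tots <- vapply(lams, function(l)
    total_loss(fixed, warped, fld, loss_config(lambda_reg = l))$total,
    numeric(1))
  expect_true(all(diff(tots) > 0))
})

test_that("loss configuration rejects invalid windows and weights", {
  expect_error(loss_config(ncc_window = 8), "odd")
  expect_error(loss_config(lambda_reg = -1), ">= 0")
  expect_error(local_ncc(rand_vol(c(4, 4, 4), 1), rand_vol(c(5, 4, 4), 1)),
               "same shape")
})
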