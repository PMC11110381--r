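test_that("phantom generation is deterministic and skull-stripped-like", {
  p <- phantom_params(shape = c(32, 32, 32), n_structures = 3, seed = 4)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)

  # background exactly zero; the mask is exactly the positive region
  expect_equal(a$mask$voxels, array(as.numeric(a$volume$voxels > 0), dim(a$mask)))
  inside <- a$mask$voxels > 0
  expect_gte(min(a$volume$voxels[inside]), 0.02)
  expect_lte(max(a$volume$voxels), 1)

  # brain occupies a plausible fraction of the grid
  frac <- mean(a$mask$voxels)
  expect_gt(frac, 0.10)
  expect_lt(frac, 0.60)

  # noiseless structure lives in [0.2, 1]
  clean <- generate_phantom(phantom_params(shape = c(32, 32, 32), seed = 4,
                                           noise_sd = 0))
  ins <- clean$mask$voxels > 0
  expect_gte(min(clean$volume$voxels[ins]), 0.2)
})

test_that("phantom parameter validation", {
  expect_error(phantom_params(shape = c(8, 32, 32)), ">= 16")
  expect_error(phantom_params(noise_sd = 0.7), "noise_sd")
  expect_error(phantom_params(lesion_radius_frac = 0.5), "lesion_radius_frac")
})

test_that("smooth fields honour amplitude, boundary shell and determinism", {
  zero <- sample_smooth_field(c(20, 20, 20), 0, 4, seed = 1)
  expect_true(all(zero$displacements == 0))

  f <- sample_smooth_field(c(32, 32, 32), 3, 6, seed = 2)
  mag <- sqrt(apply(f$displacements^2, 1:3, sum))
  expect_equal(max(mag), 3, tolerance = 1e-6)
  # 2-voxel boundary shell is pinned to zero
  expect_true(all(f$displacements[1:2, , , ] == 0))
  expect_true(all(f$displacements[, , 31:32, ] == 0))

  f2 <- sample_smooth_field(c(32, 32, 32), 3, 6, seed = 2)
  expect_identical(f$displacements, f2$displacements)
})

test_that("doubling the smoothing scale shrinks the field's gradient energy", {
  smaller <- 0
  for (seed in 1:10) {
    r1 <- diffusion_regularizer(sample_smooth_field(c(24, 24, 24), 2, 2, seed))
    r2 <- diffusion_regularizer(sample_smooth_field(c(24, 24, 24), 2, 4, seed))
    smaller <- smaller + (r2 < r1)
  }
  expect_equal(smaller, 10)
})

test_that("registration pairs carry a consistent ground truth", {
  # amplitude 0: the pair is the identical phantom twice
  p0 <- make_registration_pair(phantom_params(seed = 5, noise_sd = 0),
                               amplitude = 0, smooth_sigma = 6)
  expect_equal(p0$fixed$voxels, p0$moving$voxels)
  expect_equal(dice_score(p0$fixed_mask, p0$moving_mask), 1)

  # moderate deformation, no noise: warping moving by the true field
  # recovers fixed up to interpolation error
  p2 <- make_registration_pair(phantom_params(seed = 5, noise_sd = 0),
                               amplitude = 2, smooth_sigma = 6)
  # warping back recovers most of the attainable local correlation (the
  # self-NCC ceiling is < 1 here because flat zero-background windows
  # score 0 under the eps-stabilized squared-CC convention) and far more
  # than the unregistered moving image
  rec <- warp_volume(p2$moving, p2$true_field)
  expect_lt(mean(abs(rec$voxels - p2$fixed$voxels)), 0.02)
  ncc_self <- local_ncc(p2$fixed, p2$fixed, window = 9)
  ncc_rec <- local_ncc(p2$fixed, rec, window = 9)
  expect_gte(ncc_rec, 0.85 * ncc_self)
  expect_gt(ncc_rec, local_ncc(p2$fixed, p2$moving, window = 9))

  # larger deformation visibly moves the mask boundary
  p4 <- make_registration_pair(phantom_params(seed = 5, noise_sd = 0),
                               amplitude = 4, smooth_sigma = 6)
  expect_lt(dice_score(p4$fixed_mask, p4$moving_mask), 1)

  # masks remain 0/1 and positive only where intensity is positive
  expect_true(all(p2$moving_mask$voxels %in% c(0, 1)))
  expect_true(all(p2$moving$voxels[p2$moving_mask$voxels > 0] > 0))
})

test_that("pairs round-trip through a NIfTI directory", {
  p <- make_registration_pair(phantom_params(seed = 6), amplitude = 2,
                              smooth_sigma = 6)
  dir <- file.path(tempfile(), "pair001")
  save_registration_pair(p, dir)
  q <- load_registration_pair(dir)
  expect_equal(q$fixed$voxels, p$fixed$voxels)
  expect_equal(q$moving_mask$voxels, p$moving_mask$voxels)
  expect_equal(q$true_field$displacements, p$true_field$displacements)
})
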