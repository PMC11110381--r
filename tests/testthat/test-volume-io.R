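test_that("NIfTI round trip preserves voxels, spacing and origin", {
  set.seed(42)
  vol <- image_volume(array(rnorm(8^3), c(8, 8, 8)),
                      spacing = c(1, 1.5, 2), origin = c(-3, 0, 7))
  f <- tempfile(fileext = ".nii.gz")
  save_volume(vol, f)
  back <- load_volume(f)
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing)
  expect_equal(back$origin, vol$origin)

  zf <- tempfile(fileext = ".nii.gz")
  save_volume(image_volume(array(0, c(4, 4, 4))), zf)
  z <- load_volume(zf)
  expect_equal(dim(z), c(4, 4, 4))
  expect_true(all(z$voxels == 0))
})

test_that("degenerate volume inputs are rejected", {
  expect_error(load_volume(tempfile(fileext = ".nii")), "not found")
  f2d <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(0, 5, 5)), f2d)
  expect_error(load_volume(f2d), "3-D")
  bad <- image_volume(array(1, c(4, 4, 4)))
  bad$voxels[1] <- NaN
  expect_error(save_volume(bad, tempfile(fileext = ".nii")), "finite")
  expect_error(image_volume(array(NA_real_, c(4, 4, 4))), "finite")
  expect_error(image_volume(array(0, c(4, 4, 4)), spacing = c(1, 0, 1)),
               "positive")
})

test_that("preprocessing yields the requested shape and exact [0,1] range", {
  # full-scale shape contract: 240x240x155 cropped to 224x224x155, then 128^3
  set.seed(1)
  big <- array(0, c(240, 240, 155))
  big[60:180, 60:180, 40:120] <- runif(121^2 * 81)
  out <- preprocess_volume(image_volume(big), c(224, 224, 155), c(128, 128, 128))
  expect_equal(dim(out), c(128, 128, 128))
  expect_equal(min(out$voxels), 0)
  expect_equal(max(out$voxels), 1)

  # normalization alone maps any non-constant volume onto [0,1]
  v <- image_volume(rand_vol(c(12, 12, 12), 7))
  same <- preprocess_volume(v, c(12, 12, 12), c(12, 12, 12))
  expect_equal(min(same$voxels), 0)
  expect_equal(max(same$voxels), 1)

  expect_error(preprocess_volume(v, c(13, 12, 12), c(8, 8, 8)), "exceed")
  const <- preprocess_volume(image_volume(array(3, c(8, 8, 8))),
                             c(8, 8, 8), c(8, 8, 8))
  expect_true(all(const$voxels == 0))
})

test_that("normalization equals the closed-form z-score + min-max map", {
  ramp <- array(rep(seq(0, 1, length.out = 8), 64), c(8, 8, 8))
  out <- preprocess_volume(image_volume(ramp), c(8, 8, 8), c(8, 8, 8))
  z <- (ramp - mean(ramp)) / sd(ramp)
  expected <- (z - min(z)) / (max(z) - min(z))
  expect_equal(out$voxels, expected, tolerance = 1e-12)
})

test_that("crop centres on the nonzero bounding box", {
  arr <- array(0, c(16, 16, 16))
  arr[3:6, 9:12, 5:8] <- 1  # 4^3 block away from the centre
  out <- preprocess_volume(image_volume(arr), c(6, 6, 6), c(6, 6, 6))
  # the block fits in the crop, so all 64 nonzero voxels survive;
  # normalized output has exactly those voxels at 1
  expect_equal(sum(out$voxels == 1), 64)
})

test_that("splitting 160 subjects 64/16/20 gives 102/26/32", {
  ids <- sprintf("sub%03d", 1:160)
  for (seed in c(1, 17, 4242)) {
    sp <- split_dataset(ids, c(0.64, 0.16, 0.20), seed)
    expect_equal(lengths(sp[c("train_ids", "val_ids", "test_ids")]),
                 c(train_ids = 102L, val_ids = 26L, test_ids = 32L))
  }
})

test_that("splits partition the ids, deterministically in the seed", {
  set.seed(303)
  for (case in 1:100) {
    n <- sample(3:200, 1)
    seed <- sample.int(1e6, 1)
    f2 <- runif(1, 0, 0.4); f3 <- runif(1, 0, 0.4)
    fr <- c(1 - f2 - f3, f2, f3)
    ids <- sample(1e7, n)
    sp <- split_dataset(ids, fr, seed)
    all_ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
    expect_setequal(all_ids, ids)
    expect_equal(length(all_ids), n)  # pairwise disjoint given the union
  }
  sp1 <- split_dataset(1:50, c(0.6, 0.2, 0.2), 9)
  sp2 <- split_dataset(1:50, c(0.6, 0.2, 0.2), 9)
  sp3 <- split_dataset(1:50, c(0.6, 0.2, 0.2), 10)
  expect_identical(sp1, sp2)
  expect_false(identical(sp1$train_ids, sp3$train_ids))

  sp <- split_dataset(1:10, c(1, 0, 0), 1)
  expect_setequal(sp$train_ids, 1:10)
  expect_length(sp$val_ids, 0)
  expect_error(split_dataset(c(1, 1, 2), c(1, 0, 0), 1), "unique")
  expect_error(split_dataset(1:4, c(0.5, 0.2, 0.2), 1), "summing")
})

test_that("split manifest lists every subject once with its split", {
  sp <- split_dataset(letters[1:10], c(0.6, 0.2, 0.2), 3)
  f <- tempfile(fileext = ".csv")
  write_split_manifest(sp, f)
  df <- read.csv(f)
  expect_setequal(df$id, letters[1:10])
  expect_equal(sum(df$split == "train"), 6)
  expect_equal(sum(df$split == "val"), 2)
  expect_equal(sum(df$split == "test"), 2)
})
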