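test_that("VoxelMorph baselines have their published parameter counts", {
  vm1 <- build_voxelmorph("vm1", c(128, 128, 128))
  vm2 <- build_voxelmorph("vm2", c(128, 128, 128))
  expect_identical(count_parameters(vm1), 259675L)
  expect_identical(count_parameters(vm2), 300547L)
  expect_identical(count_parameters(vm2) - count_parameters(vm1), 40872L)
  # fully convolutional: counts are resolution-independent
  expect_identical(count_parameters(build_voxelmorph("vm1", c(32, 32, 32))),
                   259675L)
})

test_that("conv layer parameter counts follow 27 * c_in * c_out + c_out", {
  net <- build_convunet_dir(
    network_config("convunet_dir", input_shape = c(32, 32, 32)))
  enc1 <- net$steps[[1]]
  expect_identical(length(enc1$W) + length(enc1$b), 27L * 2L * 16L + 16L)  # 880
  # total equals the sum of the closed-form layer counts
  expected <- sum(vapply(net$steps, function(st)
    if (st$op == "conv") 27L * st$in_ch * st$out_ch + st$out_ch else 0L,
    integer(1)))
  expect_identical(count_parameters(net), expected)
  frozen <- net
  frozen$steps <- lapply(frozen$steps, function(st) {
    if (st$op == "conv") st$trainable <- FALSE
    st
  })
  expect_identical(count_parameters(frozen), 0L)
})

test_that("networks map a 2-channel pair to a full-resolution 3-channel field", {
  d <- c(32, 32, 32)
  fixed <- rand_vol(d, 1); moving <- rand_vol(d, 2)
  for (net in list(
    build_convunet_dir(network_config("convunet_dir", input_shape = d)),
    build_voxelmorph("vm1", d), build_voxelmorph("vm2", d))) {
    fld <- deformreg:::predict_field(net, fixed, moving)
    expect_equal(dim(fld), c(d, 3L))
  }
})

test_that("a zero-initialized flow head predicts the identity transform", {
  d <- c(16, 16, 16)
  net <- build_convunet_dir(network_config("convunet_dir", input_shape = d))
  fld <- deformreg:::predict_field(net, rand_vol(d, 3), rand_vol(d, 4))
  expect_true(all(fld$displacements == 0))
})

test_that("input shapes not divisible by 16 are rejected", {
  expect_error(network_config("convunet_dir", input_shape = c(24, 24, 24)),
               "multiples of 16")
  expect_error(build_voxelmorph("vm1", c(30, 32, 32)), "multiples of 16")
})

test_that("network backward gradients agree with finite differences", {
  # tiny custom widths keep the finite-difference loop fast
  d <- c(16, 16, 16)
  cfg <- network_config("convunet_dir", input_shape = d,
                        enc_filters = c(2, 2, 2, 2), bottleneck_filters = c(2),
                        dec_filters = c(2, 2, 2, 2), extra_filters = c(2))
  net <- build_convunet_dir(cfg, seed = 5)
  # give the flow head nonzero weights so its gradient path is generic
  flow_i <- length(net$steps)
  set.seed(6)
  net$steps[[flow_i]]$W <- matrix(rnorm(length(net$steps[[flow_i]]$W), sd = 0.05),
                                  nrow = 3)
  x <- rbind(as.numeric(rand_vol(d, 7)), as.numeric(rand_vol(d, 8)))
  attr(x, "vdim") <- d
  loss_of <- function(network) {
    fl <- deformreg:::network_forward(network, x)$flow
    sum(sin(fl))  # arbitrary smooth scalarization
  }
  fw <- deformreg:::network_forward(net, x, keep_cache = TRUE)
  grads <- deformreg:::network_backward(net, fw$cache, cos(fw$flow))
  for (i in c(1, 3, 6, flow_i)) {   # encoder, mid, decoder, flow head
    st <- net$steps[[i]]
    if (st$op != "conv") next
    set.seed(i)
    idx <- sample(length(st$W), 5)
    num <- num_grad(function(v) {
      n2 <- net; n2$steps[[i]]$W[idx] <- v; loss_of(n2)
    }, st$W[idx], h = 1e-5)
    expect_equal(as.numeric(grads[[i]]$W)[idx], num, tolerance = 1e-4)
    numb <- num_grad(function(v) {
      n2 <- net; n2$steps[[i]]$b[1] <- v; loss_of(n2)
    }, st$b[1], h = 1e-5)
    expect_equal(grads[[i]]$b[1], numb, tolerance = 1e-4)
  }
})
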