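# Shared scaled-down training runs for the end-to-end tests. Conditions
# are fixed: 8 training pairs + 1 held-out pair at 32^3, true-field
# amplitude 3 voxels (smoothness sigma 6), phantom noise sd 0.02, 30
# epochs of Adam at lr 1e-3, batch 1. The lambda = 1 and lambda = 0 runs
# share the same initialization and data order so the regularizer's
# effect is isolated. Memoized so several tests reuse one pair of runs.

.run_cache <- new.env(parent = emptyenv())

scaled_training_runs <- function() {
  if (!is.null(.run_cache$runs)) return(.run_cache$runs)
  train_pairs <- lapply(1:8, function(k)
    make_registration_pair(phantom_params(seed = k, noise_sd = 0.02),
                           amplitude = 3, smooth_sigma = 6))
  held_out <- make_registration_pair(phantom_params(seed = 99, noise_sd = 0.02),
                                     amplitude = 3, smooth_sigma = 6)
  net0 <- build_convunet_dir(
    network_config("convunet_dir", input_shape = c(32, 32, 32)), seed = 1)
  runs <- lapply(c(lambda1 = 1, lambda0 = 0), function(lam)
    train_model(net0, train_pairs, list(held_out),
                train_config(learning_rate = 1e-3, epochs = 30,
                             lambda_reg = lam, seed = 11)))
  .run_cache$runs <- list(runs = runs, train_pairs = train_pairs,
                          held_out = held_out, net0 = net0)
  .run_cache$runs
}
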