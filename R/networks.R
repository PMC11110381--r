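#' Network architecture configuration
#'
#' Declarative description of a displacement-prediction network. All
#' variants are fully convolutional encoder-decoders with 3x3x3 kernels:
#' four stride-2 encoder levels, a bottleneck, four decoder levels
#' (nearest-neighbour 2x upsampling, skip concatenation, then a stride-1
#' convolution) and a final linear 3-channel convolution emitting the
#' displacement field.
#'
#' The default filter widths mirror the VoxelMorph family scale; they are
#' configuration, so alternative widths are one call away.
#'
#' @param variant One of `"convunet_dir"`, `"vm1"`, `"vm2"`.
#' @param input_shape Integer length-3 spatial input size, each axis a
#'   multiple of 16 (four halvings).
#' @param enc_filters Four encoder filter counts.
#' @param bottleneck_filters Bottleneck filter counts (convunet_dir).
#' @param dec_filters Four decoder filter counts (convunet_dir).
#' @param extra_filters Full-resolution refinement filter counts
#'   (convunet_dir).
#' @param leaky_slope Negative slope of the LeakyReLU hidden activations.
#' @return A `network_config` list.
#' @export
network_config <- function(variant = c("convunet_dir", "vm1", "vm2"),
                           input_shape = c(128, 128, 128),
                           enc_filters = c(16, 32, 32, 32),
                           bottleneck_filters = c(32, 32),
                           dec_filters = c(32, 32, 32, 32),
                           extra_filters = c(16, 16, 16),
                           leaky_slope = 0.2) {
  variant <- match.arg(variant)
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape %% 16L != 0L) ||
      any(input_shape < 16L))
    stop("`input_shape` must be 3 multiples of 16", call. = FALSE)
  if (length(enc_filters) != 4L)
    stop("`enc_filters` must list 4 encoder levels", call. = FALSE)
  if (variant == "convunet_dir" && length(dec_filters) != 4L)
    stop("`dec_filters` must list 4 decoder levels", call. = FALSE)
  structure(list(variant = variant, input_shape = input_shape,
                 enc_filters = as.integer(enc_filters),
                 bottleneck_filters = as.integer(bottleneck_filters),
                 dec_filters = as.integer(dec_filters),
                 extra_filters = as.integer(extra_filters),
                 leaky_slope = leaky_slope),
            class = "network_config")
}

conv_step <- function(name, in_ch, out_ch, stride = 1L, act = "lrelu",
                      save = FALSE) {
  list(op = "conv", name = name, in_ch = as.integer(in_ch),
       out_ch = as.integer(out_ch), stride = as.integer(stride), act = act,
       save = save, trainable = TRUE)
}
upsample_step <- function(name) list(op = "upsample", name = name)
concat_step <- function(name, with) list(op = "concat", name = name, with = with)

plan_convunet_dir <- function(cfg) {
  f <- cfg$enc_filters; bn <- cfg$bottleneck_filters
  dc <- cfg$dec_filters; ex <- cfg$extra_filters
  steps <- list(
    conv_step("enc1", 2, f[1], stride = 2, save = TRUE),
    conv_step("enc2", f[1], f[2], stride = 2, save = TRUE),
    conv_step("enc3", f[2], f[3], stride = 2, save = TRUE),
    conv_step("enc4", f[3], f[4], stride = 2)
  )
  prev <- f[4]
  for (i in seq_along(bn)) {
    steps <- c(steps, list(conv_step(paste0("bott", i), prev, bn[i])))
    prev <- bn[i]
  }
  skips <- c("enc3", "enc2", "enc1", "input")
  skip_ch <- c(f[3], f[2], f[1], 2L)
  for (i in 1:4) {
    steps <- c(steps, list(
      upsample_step(paste0("up", i)),
      concat_step(paste0("cat", i), skips[i]),
      conv_step(paste0("dec", i), prev + skip_ch[i], dc[i])
    ))
    prev <- dc[i]
  }
  for (i in seq_along(ex)) {
    steps <- c(steps, list(conv_step(paste0("extra", i), prev, ex[i])))
    prev <- ex[i]
  }
  c(steps, list(conv_step("flow", prev, 3, act = "linear")))
}

plan_voxelmorph <- function(variant) {
  enc <- list(
    conv_step("enc1", 2, 16, stride = 2, save = TRUE),
    conv_step("enc2", 16, 32, stride = 2, save = TRUE),
    conv_step("enc3", 32, 32, stride = 2, save = TRUE),
    conv_step("enc4", 32, 32, stride = 2)
  )
  dec <- list(
    conv_step("dec0", 32, 32),
    upsample_step("up1"), concat_step("cat1", "enc3"), conv_step("dec1", 64, 32),
    upsample_step("up2"), concat_step("cat2", "enc2"), conv_step("dec2", 64, 32),
    upsample_step("up3"), concat_step("cat3", "enc1"), conv_step("dec3", 48, 32)
  )
  tail <- if (variant == "vm1") list(
    conv_step("dec4", 32, 8),
    upsample_step("up4"), concat_step("cat4", "input"),
    conv_step("dec5", 10, 8),
    conv_step("flow", 8, 3, act = "linear")
  ) else list(
    conv_step("dec4", 32, 32),
    upsample_step("up4"), concat_step("cat4", "input"),
    conv_step("dec5", 34, 16),
    conv_step("dec6", 16, 16),
    conv_step("flow", 16, 3, act = "linear")
  )
  c(enc, dec, tail)
}

init_network <- function(plan, cfg, seed) {
  with_seed(seed, {
    steps <- lapply(plan, function(st) {
      if (st$op != "conv") return(st)
      fan_in <- 27L * st$in_ch
      if (st$name == "flow") {
        # zero flow head: training starts from the identity transform
        st$W <- matrix(0, st$out_ch, fan_in)
      } else {
        st$W <- matrix(rnorm(st$out_ch * fan_in, sd = sqrt(2 / fan_in)),
                       st$out_ch, fan_in)
      }
      st$b <- numeric(st$out_ch)
      st
    })
    structure(list(config = cfg, steps = steps,
                   leaky_slope = cfg$leaky_slope),
              class = "registration_network")
  })
}

#' Build the ConvUNet-DIR registration network
#'
#' Constructs the convolutional U-Net that maps a concatenated
#' fixed/moving pair (2 input channels) to a dense 3-component
#' displacement field at the input resolution: four stride-2 3x3x3
#' encoder convolutions, a two-convolution bottleneck, four decoder
#' levels (2x nearest upsampling, skip concatenation with the matching
#' encoder feature map — the 2-channel input at full resolution — then a
#' stride-1 convolution), three full-resolution refinement convolutions,
#' and a final linear convolution to 3 channels. Hidden activations are
#' LeakyReLU; the flow head is zero-initialized so an untrained network
#' predicts the identity transform.
#'
#' @param cfg A [network_config] with `variant = "convunet_dir"`.
#' @param seed Integer seed for the weight initialization.
#' @return A `registration_network`.
#' @export
build_convunet_dir <- function(cfg = network_config("convunet_dir"), seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  if (cfg$variant != "convunet_dir")
    stop("`cfg$variant` must be \"convunet_dir\"", call. = FALSE)
  init_network(plan_convunet_dir(cfg), cfg, seed)
}

#' Build a VoxelMorph baseline network
#'
#' The VM1 and VM2 baselines share the encoder (stride-2 3x3x3
#' convolutions with 16/32/32/32 filters) and differ in the decoder: VM1
#' uses 32/32/32/32 decoder filters, an 8-filter half-resolution
#' convolution and an 8-filter full-resolution convolution after
#' concatenating the 2-channel input; VM2 widens the decoder tail
#' (an extra 32-filter half-resolution convolution, then two 16-filter
#' full-resolution convolutions). Both end in a linear 3-channel flow
#' convolution, for 259,675 (VM1) and 300,547 (VM2) trainable
#' parameters.
#'
#' @param variant `"vm1"` or `"vm2"`.
#' @param input_shape Integer length-3 input size, multiples of 16.
#' @param seed Integer seed for the weight initialization.
#' @return A `registration_network`.
#' @export
build_voxelmorph <- function(variant = c("vm1", "vm2"),
                             input_shape = c(128, 128, 128), seed = 1L) {
  variant <- match.arg(variant)
  cfg <- network_config(variant, input_shape = input_shape)
  init_network(plan_voxelmorph(variant), cfg, seed)
}

#' Count trainable parameters of a network
#'
#' @param net A `registration_network`.
#' @return Integer total of all trainable weights and biases.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "registration_network"))
  sum(vapply(net$steps, function(st) {
    if (st$op != "conv" || !isTRUE(st$trainable)) return(0L)
    length(st$W) + length(st$b)
  }, integer(1)))
}

#' @export
print.registration_network <- function(x, ...) {
  cat(sprintf("<registration_network> %s, input %s, %s trainable parameters\n",
              x$config$variant, paste(x$config$input_shape, collapse = "x"),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

lrelu <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)

# Forward pass. `x` is a (2 x N) matrix of the concatenated fixed/moving
# pair with attribute "vdim" = spatial dims. Returns the (3 x N) flow and
# (optionally) the per-step activation cache needed for backprop.
network_forward <- function(net, x, keep_cache = FALSE) {
  vdim <- attr(x, "vdim")
  saved <- list(input = list(val = x, vdim = vdim))
  cache <- if (keep_cache) vector("list", length(net$steps)) else NULL
  cur <- x
  for (i in seq_along(net$steps)) {
    st <- net$steps[[i]]
    if (st$op == "conv") {
      if (keep_cache) cache[[i]] <- list(input = cur, vdim = vdim)
      out <- conv3d_fw(st$W, st$b, cur, vdim, st$stride)
      if (st$stride == 2L) vdim <- (vdim - 1L) %/% 2L + 1L
      if (st$act == "lrelu") out <- lrelu(out, net$leaky_slope)
      if (keep_cache) cache[[i]]$output <- out
      cur <- out
      if (isTRUE(st$save)) saved[[st$name]] <- list(val = cur, vdim = vdim)
    } else if (st$op == "upsample") {
      if (keep_cache) cache[[i]] <- list(vdim_in = vdim)
      cur <- upsample2_fw(cur, vdim)
      vdim <- 2L * vdim
    } else { # concat
      sk <- saved[[st$with]]
      if (is.null(sk)) stop("unknown skip source: ", st$with, call. = FALSE)
      if (keep_cache) cache[[i]] <- list(top_rows = nrow(cur))
      cur <- rbind(cur, sk$val)
    }
  }
  attr(cur, "vdim") <- vdim
  list(flow = cur, cache = cache)
}

# Backward pass: given d loss / d flow (3 x N), returns per-step weight
# and bias gradients. Skip-connection gradients are routed back to their
# producing step; gradients into the raw input are discarded.
network_backward <- function(net, cache, grad_flow) {
  nsteps <- length(net$steps)
  grads <- vector("list", nsteps)
  pending <- list()
  g <- grad_flow
  for (i in rev(seq_len(nsteps))) {
    st <- net$steps[[i]]
    if (st$op == "conv") {
      if (isTRUE(st$save) && !is.null(pending[[st$name]]))
        g <- g + pending[[st$name]]
      if (st$act == "lrelu") {
        out <- cache[[i]]$output
        g <- g * (net$leaky_slope + (1 - net$leaky_slope) * (out > 0))
      }
      bw <- conv3d_bw(st$W, cache[[i]]$input, g, cache[[i]]$vdim, st$stride)
      grads[[i]] <- list(W = bw$grad_W, b = as.numeric(bw$grad_b))
      g <- bw$grad_input
    } else if (st$op == "upsample") {
      g <- upsample2_bw(g, cache[[i]]$vdim_in)
    } else { # concat
      tr <- cache[[i]]$top_rows
      skip_g <- g[(tr + 1):nrow(g), , drop = FALSE]
      if (st$with != "input")
        pending[[st$with]] <- if (is.null(pending[[st$with]])) skip_g
          else pending[[st$with]] + skip_g
      g <- g[seq_len(tr), , drop = FALSE]
    }
  }
  grads
}

# Predict a displacement field for a preprocessed fixed/moving pair.
predict_field <- function(net, fixed, moving) {
  fa <- as_vox_array(fixed); ma <- as_vox_array(moving)
  d <- dim(fa)
  x <- rbind(as.numeric(fa), as.numeric(ma))
  attr(x, "vdim") <- as.integer(d)
  flow <- network_forward(net, x)$flow
  field_from_matrix(t(flow), d)
}
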