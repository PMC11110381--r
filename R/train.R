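#' Training configuration
#'
#' Defaults follow standard practice for unsupervised deformable
#' registration: Adam at learning rate 1e-4, batch size 1 (one volume
#' pair per gradient step), 150 epochs, smoothness weight `lambda = 1`.
#'
#' @param learning_rate Adam step size (> 0).
#' @param epochs Number of passes over the training pairs (>= 0; 0 means
#'   return the network untouched).
#' @param batch_size Pairs per gradient step (currently 1 is supported;
#'   larger values accumulate gradients over consecutive pairs).
#' @param lambda_reg Smoothness weight of the loss.
#' @param ncc_window Odd NCC window edge length.
#' @param grad_clip Global L2-norm ceiling applied to each step's
#'   gradient before the Adam update (`Inf` disables clipping). Clipping
#'   tames the occasional large similarity gradients of batch-size-1
#'   training and permits larger learning rates in short runs.
#' @param seed Integer seed controlling data order (initialization is
#'   seeded at network build time).
#' @param checkpoint_dir Optional directory for per-run checkpoints; the
#'   best-validation weights and a JSON sidecar with the resolved
#'   configuration are written there.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 150L, batch_size = 1L,
                         lambda_reg = 1, ncc_window = 9L, grad_clip = Inf,
                         seed = 1L, checkpoint_dir = NULL) {
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (epochs < 0) stop("`epochs` must be >= 0", call. = FALSE)
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  if (grad_clip <= 0) stop("`grad_clip` must be > 0", call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lambda_reg = lambda_reg,
                 ncc_window = as.integer(ncc_window), grad_clip = grad_clip,
                 seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir,
                 adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8),
            class = "train_config")
}

adam_init <- function(net) {
  lapply(net$steps, function(st) {
    if (st$op != "conv") return(NULL)
    list(mW = matrix(0, nrow(st$W), ncol(st$W)), vW = matrix(0, nrow(st$W), ncol(st$W)),
         mb = numeric(length(st$b)), vb = numeric(length(st$b)))
  })
}

adam_update <- function(net, state, grads, t, cfg) {
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2; eps <- cfg$adam_eps
  lr_t <- cfg$learning_rate * sqrt(1 - b2^t) / (1 - b1^t)
  for (i in seq_along(net$steps)) {
    st <- net$steps[[i]]
    if (st$op != "conv" || is.null(grads[[i]])) next
    if (!isTRUE(st$trainable)) next
    s <- state[[i]]
    s$mW <- b1 * s$mW + (1 - b1) * grads[[i]]$W
    s$vW <- b2 * s$vW + (1 - b2) * grads[[i]]$W^2
    s$mb <- b1 * s$mb + (1 - b1) * grads[[i]]$b
    s$vb <- b2 * s$vb + (1 - b2) * grads[[i]]$b^2
    net$steps[[i]]$W <- st$W - lr_t * s$mW / (sqrt(s$vW) + eps)
    net$steps[[i]]$b <- st$b - lr_t * s$mb / (sqrt(s$vb) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

# Rescale a step's gradients so their global L2 norm is at most `clip`.
clip_gradients <- function(grads, clip) {
  if (!is.finite(clip)) return(grads)
  sq <- sum(vapply(grads, function(g)
    if (is.null(g)) 0 else sum(g$W^2) + sum(g$b^2), numeric(1)))
  nrm <- sqrt(sq)
  if (nrm <= clip) return(grads)
  lapply(grads, function(g) if (is.null(g)) NULL else
    list(W = g$W * (clip / nrm), b = g$b * (clip / nrm)))
}

pair_loss_and_grads <- function(net, pair, lcfg) {
  fa <- pair$fixed$voxels; ma <- pair$moving$voxels
  d <- dim(fa)
  x <- rbind(as.numeric(fa), as.numeric(ma))
  attr(x, "vdim") <- as.integer(d)
  fw <- network_forward(net, x, keep_cache = TRUE)
  fieldm <- t(fw$flow)
  field <- field_from_matrix(fieldm, d)
  warped <- array(warp_fw(as.numeric(ma), d, fieldm, FALSE), d)
  loss <- total_loss(image_volume(fa), image_volume(warped), field, lcfg)
  if (!is.finite(loss$total))
    stop("non-finite training loss (sim = ", loss$sim, ", smooth = ",
         loss$smooth, "); aborting", call. = FALSE)
  # d total / d warped = -d ncc / d warped
  g_warped <- -local_ncc_grad(fa, warped, lcfg$ncc_window, lcfg$eps)
  g_field <- warp_bw(as.numeric(ma), d, fieldm, as.numeric(g_warped))
  if (lcfg$lambda_reg > 0) {
    gs <- diffusion_grad(field)
    g_field <- g_field + matrix(gs, nrow = prod(d), ncol = 3L) * lcfg$lambda_reg
  }
  grads <- network_backward(net, fw$cache, t(g_field))
  list(loss = loss, grads = grads)
}

pair_loss_only <- function(net, pair, lcfg) {
  field <- predict_field(net, pair$fixed, pair$moving)
  warped <- warp_volume(pair$moving, field)
  total_loss(pair$fixed, warped, field, lcfg)
}

#' Train a registration network on volume pairs
#'
#' Unsupervised end-to-end training: for each pair the fixed and moving
#' volumes are concatenated into a 2-channel input, the network predicts
#' a displacement field, the moving volume is warped through the
#' differentiable trilinear transformer, and the Adam optimizer descends
#' the loss `-NCC + lambda * L_smooth`. Per-epoch training and
#' validation loss components are recorded, and the weights with the
#' best validation total loss are returned (last epoch when no
#' validation pairs are supplied).
#'
#' @param net A `registration_network`; all pairs must match its input
#'   shape.
#' @param train_pairs List of `registration_pair`s.
#' @param val_pairs List of `registration_pair`s (may be empty).
#' @param cfg A [train_config].
#' @return A list with `network` (best weights), `final_network` (last
#'   epoch), `history` (data frame: epoch, train_sim, train_smooth,
#'   train_total, val_total) and `best_epoch`.
#' @export
train_model <- function(net, train_pairs, val_pairs = list(),
                        cfg = train_config()) {
  stopifnot(inherits(net, "registration_network"), inherits(cfg, "train_config"))
  shapes <- vapply(c(train_pairs, val_pairs),
                   function(p) paste(dim(p$fixed$voxels), collapse = "x"), "")
  if (length(unique(shapes)) > 1L)
    stop("all pairs must share one shape", call. = FALSE)
  if (length(train_pairs) > 0 &&
      !all(dim(train_pairs[[1]]$fixed$voxels) == net$config$input_shape))
    stop("pair shape does not match the network input shape", call. = FALSE)
  lcfg <- loss_config(lambda_reg = cfg$lambda_reg, ncc_window = cfg$ncc_window)
  history <- data.frame(epoch = integer(), train_sim = numeric(),
                        train_smooth = numeric(), train_total = numeric(),
                        val_total = numeric())
  if (cfg$epochs == 0L || length(train_pairs) == 0L)
    return(list(network = net, final_network = net, history = history,
                best_epoch = NA_integer_))

  state <- adam_init(net)
  t_step <- 0L
  best_val <- Inf
  best_net <- net
  best_epoch <- NA_integer_
  orders <- with_seed(cfg$seed, lapply(seq_len(cfg$epochs), function(e)
    sample.int(length(train_pairs))))
  for (epoch in seq_len(cfg$epochs)) {
    sims <- smooths <- totals <- numeric(0)
    batches <- split(orders[[epoch]],
                     ceiling(seq_along(orders[[epoch]]) / cfg$batch_size))
    for (batch in batches) {
      acc <- NULL
      for (j in batch) {
        lg <- pair_loss_and_grads(net, train_pairs[[j]], lcfg)
        acc <- if (is.null(acc)) lg$grads else
          mapply(function(a, g) if (is.null(a)) NULL else
            list(W = a$W + g$W, b = a$b + g$b), acc, lg$grads, SIMPLIFY = FALSE)
        sims <- c(sims, lg$loss$sim)
        smooths <- c(smooths, lg$loss$smooth)
        totals <- c(totals, lg$loss$total)
      }
      if (length(batch) > 1L)
        acc <- lapply(acc, function(a) if (is.null(a)) NULL else
          list(W = a$W / length(batch), b = a$b / length(batch)))
      acc <- clip_gradients(acc, cfg$grad_clip)
      t_step <- t_step + 1L
      upd <- adam_update(net, state, acc, t_step, cfg)
      net <- upd$net; state <- upd$state
    }
    val_total <- if (length(val_pairs) > 0)
      mean(vapply(val_pairs, function(p) pair_loss_only(net, p, lcfg)$total,
                  numeric(1)))
    else NA_real_
    history <- rbind(history, data.frame(
      epoch = epoch, train_sim = mean(sims), train_smooth = mean(smooths),
      train_total = mean(totals), val_total = val_total))
    sel <- if (is.na(val_total)) mean(totals) else val_total
    if (sel < best_val) {
      best_val <- sel
      best_net <- net
      best_epoch <- epoch
    }
  }
  if (!is.null(cfg$checkpoint_dir)) {
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(best_net, file.path(cfg$checkpoint_dir, "best.rds"))
    saveRDS(net, file.path(cfg$checkpoint_dir, sprintf("epoch%03d.rds", cfg$epochs)))
    write.csv(history, file.path(cfg$checkpoint_dir, "history.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(cfg)[setdiff(names(cfg), "checkpoint_dir")],
           variant = net$config$variant, best_epoch = best_epoch),
      file.path(cfg$checkpoint_dir, "run.json"), auto_unbox = TRUE, digits = NA)
  }
  list(network = best_net, final_network = net, history = history,
       best_epoch = best_epoch)
}

#' Register a pair with a trained network
#'
#' A single forward pass: predicts the displacement field for the pair
#' and warps the moving volume onto the fixed one. Network parameters
#' are not modified.
#'
#' @param net A trained `registration_network`.
#' @param fixed,moving [image_volume]s preprocessed to the network's
#'   input shape.
#' @return A list with `warped` (an [image_volume]) and `field`
#'   (a [deformation_field]).
#' @export
register_pair <- function(net, fixed, moving) {
  stopifnot(inherits(net, "registration_network"))
  d <- dim(as_vox_array(fixed))
  if (!all(d == dim(as_vox_array(moving))))
    stop("fixed and moving shapes differ", call. = FALSE)
  if (!all(d == net$config$input_shape))
    stop("volumes do not match the network input shape ",
         paste(net$config$input_shape, collapse = "x"), call. = FALSE)
  field <- predict_field(net, fixed, moving)
  warped <- warp_volume(moving, field)
  list(warped = warped, field = field)
}
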