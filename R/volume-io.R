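#' Create an image volume
#'
#' An `image_volume` is a 3-D scalar voxel grid with spacing and origin
#' metadata. It is the container used for fixed images, moving images and
#' warped results throughout the package.
#'
#' @param voxels A numeric 3-D array of intensities, indexed `(x, y, z)`.
#' @param spacing Numeric length-3, millimetres per voxel along each axis.
#' @param origin Numeric length-3, physical position of voxel `(1,1,1)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array", call. = FALSE)
  if (!all(is.finite(voxels)))
    stop("volume intensities must all be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values", call. = FALSE)
  if (length(origin) != 3L)
    stop("`origin` must have length 3", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

#' Read a volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3-D image.
#' @return An [image_volume] with spacing and origin taken from the header.
#' @export
load_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D image, got ", length(dim(arr)), " dimensions", call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  image_volume(array(as.numeric(arr), dim(arr)),
               spacing = RNifti::pixdim(img)[1:3],
               origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
}

#' Write a volume to a NIfTI file
#'
#' @param vol An [image_volume].
#' @param path Destination path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  if (!all(is.finite(vol$voxels)))
    stop("volume contains non-finite intensities", call. = FALSE)
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  qf <- diag(c(vol$spacing, 1))
  qf[1:3, 4] <- vol$origin
  img <- RNifti::`qform<-`(img, structure(qf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Crop, resize and intensity-normalize a volume
#'
#' Applies the standard preprocessing chain for skull-stripped brain MR
#' volumes: (1) crop to `crop_dims`, centring the crop window on the
#' bounding box of nonzero intensities (the informative region of a
#' skull-stripped scan) and falling back to the geometric centre on any
#' axis where that box exceeds the crop size; (2) trilinear resize to
#' `out_dims`; (3) per-volume z-score normalization followed by min-max
#' rescaling to \[0, 1\].
#'
#' A constant input volume has no intensity scale and is returned as all
#' zeros (degenerate case).
#'
#' @param vol An [image_volume].
#' @param crop_dims Integer length-3 crop size, each no larger than the
#'   corresponding input dimension.
#' @param out_dims Integer length-3 output size.
#' @return An [image_volume] of size `out_dims` with intensities in
#'   \[0, 1\] (min 0, max 1 unless the input was constant). Spacing is
#'   scaled by the resize factor.
#' @export
preprocess_volume <- function(vol, crop_dims = c(224, 224, 155),
                              out_dims = c(128, 128, 128)) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$voxels)
  crop_dims <- as.integer(crop_dims)
  out_dims <- as.integer(out_dims)
  if (any(crop_dims > d))
    stop("crop_dims exceed the input dimensions", call. = FALSE)
  if (any(crop_dims < 1L) || any(out_dims < 1L))
    stop("crop_dims and out_dims must be positive", call. = FALSE)

  cropped <- crop_to_bbox(vol$voxels, crop_dims)
  scale <- dim(cropped) / out_dims
  resized <- if (all(dim(cropped) == out_dims)) cropped else
    resize_trilinear(cropped, out_dims)

  s <- sd(resized)
  if (s == 0) {
    out <- array(0, out_dims)
  } else {
    z <- (resized - mean(resized)) / s
    out <- (z - min(z)) / (max(z) - min(z))
  }
  image_volume(out, spacing = vol$spacing * scale, origin = vol$origin)
}

# Centred crop around the nonzero bounding box, per axis, clamped to the
# volume; all-zero volumes crop around the geometric centre.
crop_to_bbox <- function(arr, crop_dims) {
  d <- dim(arr)
  nz <- which(arr != 0, arr.ind = TRUE)
  idx <- vector("list", 3L)
  for (a in 1:3) {
    if (nrow(nz) == 0L) {
      centre <- (d[a] + 1) / 2
    } else {
      lo <- min(nz[, a]); hi <- max(nz[, a])
      centre <- if ((hi - lo + 1L) <= crop_dims[a]) (lo + hi) / 2 else (d[a] + 1) / 2
    }
    start <- floor(centre - crop_dims[a] / 2) + 1L
    start <- max(1L, min(start, d[a] - crop_dims[a] + 1L))
    idx[[a]] <- seq.int(start, length.out = crop_dims[a])
  }
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Trilinear resize by sampling the input at pixel-centre-aligned
# coordinates: x_in = (x_out + 0.5) * in/out - 0.5 (0-based).
resize_trilinear <- function(arr, out_dims) {
  d <- dim(arr)
  ax <- lapply(1:3, function(a) (seq_len(out_dims[a]) - 0.5) * d[a] / out_dims[a] - 0.5)
  coords <- cbind(
    rep(ax[[1]], times = out_dims[2] * out_dims[3]),
    rep(rep(ax[[2]], each = out_dims[1]), times = out_dims[3]),
    rep(ax[[3]], each = out_dims[1] * out_dims[2])
  )
  array(trilinear_sample(as.numeric(arr), d, coords), out_dims)
}

#' Randomly split subject identifiers into train/validation/test sets
#'
#' Split sizes are `round(f * n)` (half away from zero) for the validation
#' and test fractions, with the remainder assigned to training, so that
#' 160 subjects at fractions (0.64, 0.16, 0.20) give 102/26/32.
#'
#' @param ids Character or integer vector of unique subject identifiers.
#' @param fractions Numeric length-3 `(train, val, test)`, nonnegative and
#'   summing to 1.
#' @param seed Integer seed; the split is deterministic given `ids` and
#'   `seed`.
#' @return A `dataset_split` list with elements `train_ids`, `val_ids`,
#'   `test_ids` and `seed`.
#' @export
split_dataset <- function(ids, fractions = c(0.64, 0.16, 0.20), seed = 1L) {
  if (anyDuplicated(ids))
    stop("`ids` must be unique", call. = FALSE)
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("`fractions` must be 3 nonnegative values summing to 1", call. = FALSE)
  n <- length(ids)
  rhu <- function(x) floor(x + 0.5)
  n_val <- rhu(fractions[2] * n)
  n_test <- rhu(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (n_train < 0)
    stop("rounding left a negative training set; adjust fractions", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  ids <- ids[perm]
  structure(list(
    train_ids = ids[seq_len(n_train)],
    val_ids = ids[seq_len(n_val) + n_train],
    test_ids = ids[seq_len(n_test) + n_train + n_val],
    seed = as.integer(seed)
  ), class = "dataset_split")
}

#' Write a dataset split as a plain-text manifest
#'
#' One row per subject with columns `id` and `split`.
#'
#' @param split A `dataset_split` from [split_dataset()].
#' @param path Destination CSV path.
#' @return Invisibly, the manifest data frame.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  df <- data.frame(
    id = c(split$train_ids, split$val_ids, split$test_ids),
    split = rep(c("train", "val", "test"),
                c(length(split$train_ids), length(split$val_ids),
                  length(split$test_ids)))
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
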