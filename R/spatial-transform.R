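#' Create a deformation field
#'
#' A dense displacement field `s` over a voxel grid: a 4-D array of shape
#' `(X, Y, Z, 3)` whose last axis holds the components `(dx, dy, dz)` in
#' voxel units. Together with the identity grid it defines the mapping
#' `phi(x) = x + s(x)` used to warp a moving image onto a fixed image.
#'
#' @param displacements Numeric 4-D array `(X, Y, Z, 3)`.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(displacements) {
  d <- dim(displacements)
  if (length(d) != 4L || d[4] != 3L)
    stop("`displacements` must be a 4-D array with last dimension 3", call. = FALSE)
  if (!all(is.finite(displacements)))
    stop("displacements must all be finite", call. = FALSE)
  structure(list(displacements = displacements), class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  d <- dim(x$displacements)
  mag <- sqrt(rowSums(field_matrix(x)^2))
  cat(sprintf("<deformation_field> %d x %d x %d, |s| mean %.3g max %.3g voxels\n",
              d[1], d[2], d[3], mean(mag), max(mag)))
  invisible(x)
}

#' @export
dim.deformation_field <- function(x) dim(x$displacements)

# Field as an N x 3 matrix (voxel-major, x fastest), the layout the C++
# warping kernels expect.
field_matrix <- function(field) {
  d <- dim(field$displacements)
  matrix(field$displacements, nrow = prod(d[1:3]), ncol = 3L)
}

field_from_matrix <- function(m, shape) {
  deformation_field(array(m, c(shape, 3L)))
}

#' Identity sampling grid
#'
#' Voxel-centre coordinates `g[i, j, k, ] = (i, j, k)` (0-based, voxel
#' units); the grid to which a displacement field is added to obtain the
#' sampling map `phi`.
#'
#' @param shape Integer length-3 grid size.
#' @return A numeric 4-D array `(X, Y, Z, 3)`.
#' @export
identity_grid <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be 3 positive integers", call. = FALSE)
  g <- array(0, c(shape, 3L))
  g[, , , 1] <- rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3])
  g[, , , 2] <- rep(rep(seq_len(shape[2]) - 1, each = shape[1]), times = shape[3])
  g[, , , 3] <- rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2])
  g
}

#' Warp a volume with a displacement field
#'
#' Computes the spatially transformed image `I(phi)` with
#' `phi(x) = x + s(x)`: each output voxel takes the value of the input
#' sampled at its displaced position, by trilinear interpolation
#' (intensities) or nearest-neighbour lookup (binary masks). Sampling
#' positions outside the grid are clamped to the border (edge
#' replication). The trilinear path is differentiable with respect to
#' both intensities and displacements; its coordinate gradient backs the
#' training engine.
#'
#' @param vol An [image_volume] (or bare 3-D array).
#' @param field A [deformation_field] with the same spatial shape.
#' @param mode `"trilinear"` (default) or `"nearest"`.
#' @return An [image_volume] of the same shape.
#' @export
warp_volume <- function(vol, field, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  arr <- if (inherits(vol, "image_volume")) vol$voxels else vol
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  if (!inherits(field, "deformation_field"))
    stop("`field` must be a deformation_field", call. = FALSE)
  d <- dim(arr)
  if (!all(dim(field)[1:3] == d))
    stop("field shape does not match the volume", call. = FALSE)
  out <- array(warp_fw(as.numeric(arr), d, field_matrix(field),
                       mode == "nearest"), d)
  if (inherits(vol, "image_volume"))
    image_volume(out, spacing = vol$spacing, origin = vol$origin)
  else out
}

#' Save a deformation field as 4-D NIfTI
#'
#' The last axis holds the three displacement components in voxel units.
#'
#' @param field A [deformation_field].
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
save_field <- function(field, path) {
  stopifnot(inherits(field, "deformation_field"))
  img <- RNifti::asNifti(field$displacements)
  img$descrip <- "displacement field, voxel units, components (dx,dy,dz)"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a deformation field from 4-D NIfTI
#'
#' @param path Path to a 4-D NIfTI whose last axis has length 3.
#' @return A [deformation_field].
#' @export
load_field <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop("expected a 4-D field with last axis of length 3", call. = FALSE)
  deformation_field(array(as.numeric(arr), dim(arr)))
}
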