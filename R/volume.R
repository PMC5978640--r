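# ReconVolume: a 3D intensity grid with voxel spacings and a chest-wall
# anchored coordinate frame. Array layout is [slice, row, col] = [z, y, x];
# row 1 adjoins the chest-wall edge.

#' Reconstructed volume container
#'
#' @param data numeric 3D array indexed \code{[slice, row, col]}.
#' @param spacing voxel spacings \code{c(dz, dy, dx)} in mm.
#' @param origin world coordinates \code{c(x, y, z)} in mm of voxel
#'   \code{[1, 1, 1]} (y measured from the chest wall).
#' @param metadata named list of acquisition metadata (mAs, nominal slice
#'   width, ...).
#' @return An object of class \code{recon_volume}.
#' @export
recon_volume <- function(data, spacing, origin = c(x = 0, y = 0, z = 0),
                         metadata = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(spacing <= 0)) stopf("voxel spacings must be > 0")
  if (!all(is.finite(data))) stopf("volume intensities must be finite")
  v <- list(data = data,
            spacing = c(dz = spacing[[1]], dy = spacing[[2]], dx = spacing[[3]]),
            origin = c(x = origin[[1]], y = origin[[2]], z = origin[[3]]),
            metadata = metadata)
  class(v) <- "recon_volume"
  v
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("recon_volume: %d slices x %d rows x %d cols\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (dz, dy, dx): %g, %g, %g mm\n",
              x$spacing["dz"], x$spacing["dy"], x$spacing["dx"]))
  cat(sprintf("  origin (x, y, z): %g, %g, %g mm\n",
              x$origin["x"], x$origin["y"], x$origin["z"]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.recon_volume <- function(x) dim(x$data)

# world coordinates of voxel centers along each axis
vol_x <- function(v) v$origin[["x"]] + (seq_len(dim(v$data)[3]) - 1) * v$spacing[["dx"]]
vol_y <- function(v) v$origin[["y"]] + (seq_len(dim(v$data)[2]) - 1) * v$spacing[["dy"]]
vol_z <- function(v) v$origin[["z"]] + (seq_len(dim(v$data)[1]) - 1) * v$spacing[["dz"]]

# nearest voxel indices for world coordinates (clamped into the grid when
# clamp = TRUE, NA outside otherwise)
world_to_col <- function(v, x, clamp = FALSE) {
  i <- round((x - v$origin[["x"]]) / v$spacing[["dx"]]) + 1
  n <- dim(v$data)[3]
  if (clamp) pmin(pmax(i, 1), n) else ifelse(i >= 1 & i <= n, i, NA_real_)
}
world_to_row <- function(v, y, clamp = FALSE) {
  i <- round((y - v$origin[["y"]]) / v$spacing[["dy"]]) + 1
  n <- dim(v$data)[2]
  if (clamp) pmin(pmax(i, 1), n) else ifelse(i >= 1 & i <= n, i, NA_real_)
}
world_to_slice <- function(v, z, clamp = FALSE) {
  i <- round((z - v$origin[["z"]]) / v$spacing[["dz"]]) + 1
  n <- dim(v$data)[1]
  if (clamp) pmin(pmax(i, 1), n) else ifelse(i >= 1 & i <= n, i, NA_real_)
}

# extract a 2D slice as a plain matrix [row, col]
vol_slice <- function(v, s) v$data[s, , ]

# mean/SD over a disc ROI on one slice; returns list(mean, sd, n, pixels)
disc_stats <- function(v, slice, cx, cy, radius) {
  xs <- vol_x(v); ys <- vol_y(v)
  ci <- which(abs(xs - cx) <= radius)
  ri <- which(abs(ys - cy) <= radius)
  if (!length(ci) || !length(ri)) stopf("ROI lies outside the volume")
  sub <- v$data[slice, ri, ci, drop = TRUE]
  if (is.null(dim(sub))) sub <- matrix(sub, length(ri), length(ci))
  msk <- outer((ys[ri] - cy)^2, (xs[ci] - cx)^2, "+") <= radius^2
  px <- sub[msk]
  if (!length(px)) stopf("ROI contains no pixels")
  list(mean = mean(px), sd = stats::sd(px), n = length(px))
}
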