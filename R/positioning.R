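# Phantom positioning: locate the alignment markers and estimate roll,
# pitch, and yaw by rigid registration, so downstream ROIs can be placed
# pose-corrected and misalignment is reported as a metric of its own.

#' Locate the alignment markers in a volume
#'
#' Searches a window around each marker's nominal (geometry) position,
#' thresholds halfway between local background and the local peak, and
#' takes the intensity-weighted center of mass of the voxels above
#' threshold, giving sub-voxel centroids.
#'
#' @param volume a \code{recon_volume}.
#' @param geometry a \code{phantom_geometry} (for nominal marker positions).
#' @param search_mm half-width of the search window around each nominal
#'   position (mm); must exceed the expected misalignment.
#' @param min_voxels minimum above-threshold voxels for a marker to count
#'   as found.
#' @return Matrix (n x 3, columns x/y/z in mm) of marker centroids, in the
#'   order of \code{geometry$alignment_markers}.
#' @export
locate_markers <- function(volume, geometry, search_mm = 6, min_voxels = 5L) {
  mk <- geometry$alignment_markers
  xs <- vol_x(volume); ys <- vol_y(volume); zs <- vol_z(volume)
  found <- matrix(NA_real_, nrow(mk), 3,
                  dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(nrow(mk))) {
    ci <- which(abs(xs - mk$x[i]) <= search_mm)
    ri <- which(abs(ys - mk$y[i]) <= search_mm)
    si <- which(abs(zs - mk$z[i]) <= search_mm)
    if (!length(ci) || !length(ri) || !length(si)) next
    sub <- volume$data[si, ri, ci, drop = FALSE]
    bg <- stats::median(sub)
    pk <- max(sub)
    if (pk <= bg) next
    thr <- bg + 0.5 * (pk - bg)
    idx <- which(sub > thr, arr.ind = TRUE)
    if (nrow(idx) < min_voxels) next
    w <- sub[idx] - bg
    found[i, ] <- c(sum(w * xs[ci][idx[, 3]]) / sum(w),
                    sum(w * ys[ri][idx[, 2]]) / sum(w),
                    sum(w * zs[si][idx[, 1]]) / sum(w))
  }
  ok <- stats::complete.cases(found)
  if (!all(ok))
    stopf("found %d of %d expected alignment markers (missing: %s)",
          sum(ok), nrow(mk), paste(which(!ok), collapse = ", "))
  found
}

#' Estimate phantom pose from marker centroids
#'
#' Least-squares rigid registration (orthogonal Procrustes) of the measured
#' marker centroids onto their geometry positions, with rotation angles
#' extracted in the fixed z-y-x (yaw-pitch-roll) intrinsic convention, in
#' degrees. The returned transform maps geometry coordinates into volume
#' coordinates, so downstream modules can place pose-corrected ROIs by
#' coordinate transform alone (intensities are never resampled).
#'
#' @param centroids n x 3 matrix of measured marker positions (mm), ordered
#'   as the geometry's marker table.
#' @param geometry a \code{phantom_geometry}.
#' @return An object of class \code{pose_estimate} with elements
#'   \code{roll}, \code{pitch}, \code{yaw} (degrees), \code{translation}
#'   (x, y, mm), \code{rotation} (3x3), \code{center} (rotation center),
#'   \code{residual_mm} (RMS registration residual) and \code{reliable}
#'   (per-axis flags; an axis is flagged unreliable beyond 15 degrees).
#' @export
estimate_pose <- function(centroids, geometry) {
  ref <- as.matrix(geometry$alignment_markers[, c("x", "y", "z")])
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 3 || nrow(centroids) != nrow(ref))
    stopf("need >= 3 marker centroids matching the geometry's markers")
  # collinearity check via rank of the centered reference
  cen <- scale(ref, scale = FALSE)
  if (sum(svd(cen)$d > 1e-8) < 2) stopf("markers are collinear")

  center <- geometry_center(geometry)
  A <- sweep(ref, 2, center)            # geometry frame
  B <- sweep(centroids, 2, center)      # measured frame
  mA <- colMeans(A); mB <- colMeans(B)
  H <- t(sweep(A, 2, mA)) %*% sweep(B, 2, mB)
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)           # maps geometry -> measured
  t3 <- mB - as.vector(R %*% mA)

  # z-y-x (yaw-pitch-roll) extraction: R = Rz(yaw) Ry(pitch) Rx(roll)
  pitch <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(pitch)) > 1e-8) {
    yaw <- atan2(R[2, 1], R[1, 1])
    roll <- atan2(R[3, 2], R[3, 3])
  } else {  # gimbal degenerate; report yaw only
    yaw <- atan2(-R[1, 2], R[2, 2])
    roll <- 0
  }
  ang <- c(roll = roll, pitch = pitch, yaw = yaw) * 180 / pi
  fitted <- sweep(A %*% t(R), 2, t3, "+")
  residual <- sqrt(mean(rowSums((fitted - B)^2)))

  out <- list(roll = ang[["roll"]], pitch = ang[["pitch"]],
              yaw = ang[["yaw"]],
              translation = c(x = unname(t3[1]), y = unname(t3[2])),
              rotation = R, center = center,
              residual_mm = residual,
              reliable = abs(ang) < 15)
  class(out) <- "pose_estimate"
  out
}

#' Identity pose
#' @param geometry a \code{phantom_geometry} (fixes the rotation center).
#' @export
identity_pose <- function(geometry) {
  out <- list(roll = 0, pitch = 0, yaw = 0,
              translation = c(x = 0, y = 0),
              rotation = diag(3), center = geometry_center(geometry),
              residual_mm = 0, reliable = c(roll = TRUE, pitch = TRUE,
                                            yaw = TRUE))
  class(out) <- "pose_estimate"
  out
}

#' Map phantom coordinates to volume coordinates under a pose
#'
#' @param pts n x 3 matrix or data.frame with x/y/z columns, in phantom
#'   (geometry) coordinates.
#' @param pose a \code{pose_estimate} (or \code{NULL} for identity).
#' @return n x 3 matrix of pose-corrected coordinates (mm).
#' @export
pose_apply <- function(pts, pose = NULL) {
  p <- as.matrix(as.data.frame(pts)[, c("x", "y", "z"), drop = FALSE])
  if (is.null(pose)) return(p)
  stopifnot(inherits(pose, "pose_estimate"))
  out <- sweep(p, 2, pose$center) %*% t(pose$rotation)
  out <- sweep(out, 2, pose$center, "+")
  out[, 1] <- out[, 1] + pose$translation[["x"]]
  out[, 2] <- out[, 2] + pose$translation[["y"]]
  colnames(out) <- c("x", "y", "z")
  out
}

# convenience: pose-correct a single (x, y, z) point
pose_point <- function(x, y, z, pose = NULL) {
  as.numeric(pose_apply(data.frame(x = x, y = y, z = z), pose))
}

#' @export
print.pose_estimate <- function(x, ...) {
  cat(sprintf("pose estimate: roll %.3f deg, pitch %.3f deg, yaw %.3f deg\n",
              x$roll, x$pitch, x$yaw))
  cat(sprintf("  translation: (%.3f, %.3f) mm; RMS residual %.4f mm\n",
              x$translation[["x"]], x$translation[["y"]], x$residual_mm))
  if (!all(x$reliable))
    cat("  WARNING: estimate flagged unreliable for:",
        paste(names(x$reliable)[!x$reliable], collapse = ", "), "\n")
  invisible(x)
}
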