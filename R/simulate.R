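# Synthetic phantom-volume simulator. Renders the analytic solids of the
# geometry through the acquisition model's slice profile, in-plane blur,
# and mAs-scaled noise, and keeps a ground-truth record alongside the
# rendered volume for use by analysis tests.

#' Rigid rotation matrix in the z-y-x (yaw-pitch-roll) convention
#'
#' @param roll,pitch,yaw angles in degrees about x, y, z respectively;
#'   composed as Rz(yaw) Ry(pitch) Rx(roll).
#' @return 3x3 rotation matrix acting on (x, y, z) column vectors.
#' @export
rotation_zyx <- function(roll, pitch, yaw) {
  r <- roll * pi / 180; p <- pitch * pi / 180; w <- yaw * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3, 3)
  Ry <- matrix(c(cos(p), 0, -sin(p), 0, 1, 0, sin(p), 0, cos(p)), 3, 3)
  Rz <- matrix(c(cos(w), sin(w), 0, -sin(w), cos(w), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# apply pose (rotation about `center`, then in-plane translation) to an
# n x 3 matrix / data.frame of xyz points
apply_rigid <- function(pts, pose_deg, translation_mm, center) {
  p <- as.matrix(pts[, c("x", "y", "z"), drop = FALSE])
  R <- rotation_zyx(pose_deg[1], pose_deg[2], pose_deg[3])
  out <- sweep(p, 2, center) %*% t(R)
  out <- sweep(out, 2, center, "+")
  out[, 1] <- out[, 1] + translation_mm[1]
  out[, 2] <- out[, 2] + translation_mm[2]
  colnames(out) <- c("x", "y", "z")
  out
}

# collect every renderable solid: data.frame of spheres and list of boxes
collect_solids <- function(geometry) {
  sph <- list()
  add_sph <- function(df, what) {
    if (nrow(df))
      sph[[length(sph) + 1L]] <<- data.frame(
        x = df$x, y = df$y, z = df$z, r = df$diameter / 2,
        contrast = df$contrast, what = what)
  }
  for (r in geometry$ramps) {
    bp <- bead_positions(r)
    bp$diameter <- r$bead_diameter
    bp$contrast <- r$contrast
    add_sph(bp, paste0("ramp_", r$side))
  }
  add_sph(geometry$z_beads, "z_bead")
  add_sph(geometry$low_contrast_spheres, "sphere")
  add_sph(geometry$alignment_markers, "marker")
  spheres <- if (length(sph)) do.call(rbind, sph) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               r = numeric(0), contrast = numeric(0), what = character(0))

  boxes <- list()
  for (g in geometry$gauges) {
    for (k in seq_len(g$n_steps)) {
      boxes[[length(boxes) + 1L]] <- list(
        x = g$lateral_position, y = (k - 0.5) * g$step_increment,
        z = g$z_center, hx = g$width / 2, hy = g$step_increment / 2,
        hz = g$thickness / 2, contrast = g$contrast,
        what = paste0(g$id, "_step", k))
    }
  }
  sq <- geometry$al_square
  boxes[[length(boxes) + 1L]] <- list(
    x = sq$center[["x"]], y = sq$center[["y"]], z = sq$center[["z"]],
    hx = sq$side / 2, hy = sq$side / 2, hz = sq$thickness / 2,
    contrast = sq$contrast, what = "al_square")

  list(spheres = spheres, boxes = boxes)
}

# fractional 1D coverage of pixels (centers `cent`, width `d`) by [lo, hi]
coverage_1d <- function(cent, d, lo, hi) {
  pmax(0, pmin(cent + d / 2, hi) - pmax(cent - d / 2, lo)) / d
}

# separable Gaussian blur of one slice; edges handled by replicate padding
blur_slice <- function(m, sigma_row_px, sigma_col_px) {
  conv_cols <- function(mat, sigma) {
    if (sigma <= 0) return(mat)
    rad <- max(1L, ceiling(4 * sigma))
    k <- stats::dnorm(seq(-rad, rad), sd = sigma)
    k <- k / sum(k)
    n <- nrow(mat)
    padded <- rbind(mat[rep(1L, rad), , drop = FALSE], mat,
                    mat[rep(n, rad), , drop = FALSE])
    f <- stats::filter(padded, k, method = "convolution", sides = 2)
    matrix(f[(rad + 1):(rad + n), ], nrow = n)
  }
  m <- conv_cols(m, sigma_row_px)
  t(conv_cols(t(m), sigma_col_px))
}

#' Render a synthetic reconstructed volume of the phantom
#'
#' Every object is rendered as its analytic solid: the through-plane extent
#' is integrated against the slice profile in closed form, the in-plane
#' cross-section is sampled on a 3x supersampled grid and box-averaged
#' (avoiding aliasing of the 0.18 mm ramp beads on ~0.1 mm pixels), the
#' slice is then convolved with the anisotropic in-plane blur, and Gaussian
#' noise with SD = base_sd * (mAs/ref_mas)^exponent is added per voxel.
#' Pose is applied as a rigid rotation of object positions about the phantom
#' center plus an in-plane translation -- coordinates move, intensities are
#' never resampled.
#'
#' @param geometry a \code{phantom_geometry}.
#' @param acq an \code{acquisition_model}.
#' @param region optional list with \code{min} and \code{max} xyz vectors
#'   (mm) selecting a sub-volume to render (e.g. a chest-wall crop or just
#'   the bead-ramp strip); default is the full phantom bounding box. Must
#'   intersect the phantom.
#' @param supersample in-plane supersampling factor (default 3).
#' @return A \code{\link{recon_volume}} whose \code{"truth"} attribute
#'   records the posed object positions, true slice width, noise SD and
#'   pose used (see \code{\link{render_truth}}).
#' @export
render <- function(geometry, acq, region = NULL, supersample = 3L) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(acq, "acquisition_model"))
  bb <- geometry_bbox(geometry)
  if (is.null(region)) region <- bb
  rmin <- region$min; rmax <- region$max
  if (any(rmax <= rmin)) stopf("render region has non-positive extent")
  if (any(rmax < bb$min) || any(rmin > bb$max))
    stopf("render grid does not cover the phantom bounding box")

  dxy <- acq$pixel_spacing_xy; dz <- acq$slice_increment
  nx <- max(1L, floor((rmax[["x"]] - rmin[["x"]]) / dxy))
  ny <- max(1L, floor((rmax[["y"]] - rmin[["y"]]) / dxy))
  nz <- max(1L, floor((rmax[["z"]] - rmin[["z"]]) / dz) + 1L)
  origin <- c(x = rmin[["x"]] + dxy / 2, y = rmin[["y"]] + dxy / 2,
              z = rmin[["z"]])
  xs <- origin[["x"]] + (seq_len(nx) - 1) * dxy
  ys <- origin[["y"]] + (seq_len(ny) - 1) * dxy
  zs <- origin[["z"]] + (seq_len(nz) - 1) * dz

  bg <- acq$background_level
  vol <- array(bg, dim = c(nz, ny, nx))

  center <- geometry_center(geometry)
  solids <- collect_solids(geometry)
  sph <- solids$spheres
  if (nrow(sph)) {
    sp_pos <- apply_rigid(sph, acq$pose_deg, acq$translation_mm, center)
    sph$x <- sp_pos[, "x"]; sph$y <- sp_pos[, "y"]; sph$z <- sp_pos[, "z"]
  }
  boxes <- lapply(solids$boxes, function(b) {
    p <- apply_rigid(data.frame(x = b$x, y = b$y, z = b$z),
                     acq$pose_deg, acq$translation_mm, center)
    b$x <- p[1, "x"]; b$y <- p[1, "y"]; b$z <- p[1, "z"]
    b
  })

  Fcdf <- profile_cdf(acq$slice_profile, acq$nominal_slice_width)
  pnorm_tot <- profile_norm(acq$slice_profile, acq$nominal_slice_width)
  hs <- profile_halfsupport(acq$slice_profile, acq$nominal_slice_width)
  ss <- as.integer(supersample)

  Sfun <- profile_fun(acq$slice_profile, acq$nominal_slice_width)

  # spheres: supersampled in-plane, closed-form chord integral in z
  for (i in seq_len(nrow(sph))) {
    cx <- sph$x[i]; cy <- sph$y[i]; cz <- sph$z[i]
    R <- sph$r[i]; amp <- bg * sph$contrast[i]
    ci <- which(abs(xs - cx) <= R + dxy)
    ri <- which(abs(ys - cy) <= R + dxy)
    if (!length(ci) || !length(ri)) next
    si <- which(abs(zs - cz) <= R + hs)
    if (!length(si)) next
    if (2 * R < dxy / supersample) {
      # below the supersampling resolution: deposit the sphere's integral
      # as a point source, bilinearly split over the 4 nearest pixels
      vol_sph <- 4 / 3 * pi * R^3
      fx <- (cx - xs[1]) / dxy; fy <- (cy - ys[1]) / dxy
      i0 <- floor(fx); j0 <- floor(fy)
      wx <- fx - i0; wy <- fy - j0
      for (s in si) {
        a <- amp * vol_sph * Sfun(cz - zs[s]) / (pnorm_tot * dxy^2)
        for (dxi in 0:1) for (dyi in 0:1) {
          ii <- i0 + dxi + 1L; jj <- j0 + dyi + 1L
          if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny)
            vol[s, jj, ii] <- vol[s, jj, ii] +
              a * (if (dxi) wx else 1 - wx) * (if (dyi) wy else 1 - wy)
        }
      }
      next
    }
    off <- (seq_len(ss) - (ss + 1) / 2) * dxy / ss
    fx <- rep(xs[ci], each = ss) + rep(off, length(ci))
    fy <- rep(ys[ri], each = ss) + rep(off, length(ri))
    rho2 <- outer((fy - cy)^2, (fx - cx)^2, "+")
    h <- sqrt(pmax(R^2 - rho2, 0))
    inside <- rho2 < R^2
    for (s in si) {
      w <- matrix(0, nrow(rho2), ncol(rho2))
      w[inside] <- (Fcdf(cz + h[inside] - zs[s]) -
                    Fcdf(cz - h[inside] - zs[s])) / pnorm_tot
      # box-average the supersampled grid back to the pixel grid
      dim(w) <- c(ss, length(ri), ss, length(ci))
      w2 <- colMeans(w)                     # (ri, ss, ci)
      wpix <- colMeans(aperm(w2, c(2, 1, 3)))  # (ri, ci)
      vol[s, ri, ci] <- vol[s, ri, ci] + amp * wpix
    }
  }

  # boxes: analytic fractional pixel coverage in x and y, chord in z
  for (b in boxes) {
    amp <- bg * b$contrast
    covx <- coverage_1d(xs, dxy, b$x - b$hx, b$x + b$hx)
    covy <- coverage_1d(ys, dxy, b$y - b$hy, b$y + b$hy)
    ci <- which(covx > 0); ri <- which(covy > 0)
    if (!length(ci) || !length(ri)) next
    si <- which(abs(zs - b$z) <= b$hz + hs)
    xyw <- outer(covy[ri], covx[ci])
    for (s in si) {
      wz <- (Fcdf(b$z + b$hz - zs[s]) - Fcdf(b$z - b$hz - zs[s])) / pnorm_tot
      vol[s, ri, ci] <- vol[s, ri, ci] + amp * wz * xyw
    }
  }

  # in-plane blur, then noise (noise is post-reconstruction, not blurred)
  sr <- acq$blur_sigma_y / dxy
  sc <- acq$blur_sigma_x / dxy
  if (sr > 0 || sc > 0) {
    for (s in seq_len(nz)) vol[s, , ] <- blur_slice(vol[s, , ], sr, sc)
  }
  sdn <- noise_sd(acq)
  if (sdn > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(acq$seed)
    vol <- vol + array(stats::rnorm(length(vol), 0, sdn), dim = dim(vol))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }

  meta <- list(mas = acq$mas, nominal_slice_width = acq$nominal_slice_width,
               slice_profile = acq$slice_profile, seed = acq$seed,
               background_level = bg, source = "tomoqa-simulator")
  out <- recon_volume(vol, spacing = c(dz, dxy, dxy), origin = origin,
                      metadata = meta)

  truth <- list(
    pose_deg = acq$pose_deg, translation_mm = acq$translation_mm,
    rotation_center = center,
    slice_width = acq$nominal_slice_width,
    slice_profile = acq$slice_profile,
    slice_increment = dz, pixel_spacing = dxy,
    noise_sd = sdn, background_level = bg, mas = acq$mas,
    markers = apply_rigid(geometry$alignment_markers, acq$pose_deg,
                          acq$translation_mm, center),
    z_beads = apply_rigid(geometry$z_beads, acq$pose_deg,
                          acq$translation_mm, center),
    region = list(min = rmin, max = rmax), seed = acq$seed)
  attr(out, "truth") <- truth
  out
}

#' Ground-truth record of a rendered volume
#' @param volume a \code{recon_volume} produced by \code{\link{render}}.
#' @return The truth list (pose, slice width, posed marker and bead
#'   positions, noise SD, ...), or \code{NULL} for volumes read from disk
#'   without a truth sidecar.
#' @export
render_truth <- function(volume) attr(volume, "truth")

#' Render a series of volumes over an mAs sweep
#'
#' One volume per mAs value; each realization gets a seed derived
#' deterministically from the base seed so the series is reproducible.
#'
#' @param geometry a \code{phantom_geometry}.
#' @param acq an \code{acquisition_model}; its \code{mas} field is replaced
#'   per element of \code{mas_list}.
#' @param mas_list numeric vector of positive mAs values.
#' @inheritParams render
#' @return List of \code{recon_volume}s, one per mAs.
#' @export
render_series <- function(geometry, acq, mas_list, region = NULL,
                          supersample = 3L) {
  if (!length(mas_list) || any(mas_list <= 0))
    stopf("mas_list must be non-empty and positive")
  lapply(seq_along(mas_list), function(i) {
    a <- acq
    a$mas <- mas_list[i]
    a$seed <- as.integer((acq$seed + 7919 * (i - 1)) %% 2147483647)
    render(geometry, a, region = region, supersample = supersample)
  })
}
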