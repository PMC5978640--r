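# Uniformity, SNR, CNR and the noise-versus-mAs power law. Pixel value
# scales are vendor-specific in DBT (no portable unit akin to Hounsfield
# units exists), so all contrast metrics here are ratios or percent
# differences, never absolute units.

#' Default uniformity/noise ROI layout
#'
#' Fixed ROI centers (phantom coordinates, mm) chosen to keep every ROI
#' clear of all test objects with a 2 mm margin: two large regional ROIs
#' (10 mm radius, anterior and lateral), five global-uniformity ROIs (5 mm
#' radius), an SNR pair (uniform + neighboring noise ROI) and the CNR
#' background ROI. Approximate by construction -- placements are
#' configurable where a site's phantom or field differs.
#'
#' @param geometry a \code{phantom_geometry} (placements validated
#'   against it).
#' @return List of data.frames: \code{regional}, \code{global_rois},
#'   \code{snr} and \code{cnr_background}, each with x, y, radius.
#' @export
default_rois <- function(geometry) {
  rois <- list(
    regional = data.frame(id = c("anterior", "lateral"),
                          x = c(30, -39), y = c(65, 38), radius = 10),
    global_rois = data.frame(id = paste0("g", 1:5),
                             x = c(-25, 25, -30, 5, 30),
                             y = c(15, 15, 60, 72, 47), radius = 5),
    snr = data.frame(id = c("signal", "noise"),
                     x = c(-30, -22), y = c(60, 66), radius = 5),
    cnr_background = data.frame(id = "cnr_bg", x = 30, y = 47, radius = 5))
  rois
}

check_rois_clear <- function(rois_df, geometry, dilation_mm = 2) {
  for (i in seq_len(nrow(rois_df))) {
    ok <- roi_is_clear(rois_df$x[i], rois_df$y[i], rois_df$radius[i],
                       geometry, dilation_mm = dilation_mm)
    if (!ok)
      stopf("ROI '%s' at (%g, %g) overlaps test object(s): %s",
            rois_df$id[i], rois_df$x[i], rois_df$y[i],
            paste(attr(ok, "blocking"), collapse = ", "))
  }
  invisible(TRUE)
}

roi_center_posed <- function(roi_x, roi_y, z, pose) {
  pose_point(roi_x, roi_y, z, pose)
}

#' Regional uniformity across slices
#'
#' Mean and SD of the pixel values in two large (10 mm radius) ROIs, placed
#' anterior and lateral, computed per reconstructed slice so trends across
#' the slice (z) dimension are visible.
#'
#' @param volume a \code{recon_volume}.
#' @param geometry a \code{phantom_geometry}.
#' @param pose a \code{pose_estimate} or \code{NULL}.
#' @param rois optional data.frame overriding the regional ROIs
#'   (\code{id}, \code{x}, \code{y}, \code{radius}).
#' @param slices slice indices to measure (default all).
#' @return data.frame with columns roi, slice, z_mm, mean, sd, n_pixels;
#'   attribute \code{"trend"} holds the fitted linear slope of each ROI's
#'   mean versus z (units per mm).
#' @export
regional_uniformity <- function(volume, geometry, pose = NULL, rois = NULL,
                                slices = NULL) {
  rois <- rois %||% default_rois(geometry)$regional
  check_rois_clear(rois, geometry)
  slices <- slices %||% seq_len(dim(volume$data)[1])
  zs <- vol_z(volume)
  out <- list()
  for (i in seq_len(nrow(rois))) {
    for (s in slices) {
      ctr <- roi_center_posed(rois$x[i], rois$y[i], zs[s], pose)
      st <- disc_stats(volume, s, ctr[1], ctr[2], rois$radius[i])
      out[[length(out) + 1L]] <- data.frame(
        roi = rois$id[i], slice = s, z_mm = zs[s], mean = st$mean,
        sd = st$sd, n_pixels = st$n)
    }
  }
  df <- do.call(rbind, out)
  trend <- vapply(unique(df$roi), function(r) {
    sub <- df[df$roi == r, ]
    if (nrow(sub) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(mean ~ z_mm, data = sub))[2])
  }, numeric(1))
  attr(df, "trend") <- trend
  df
}

#' Global uniformity of one slice
#'
#' Five 5 mm-radius ROIs; the metric is the maximum absolute difference
#' between ROI means, expressed as a percentage of the grand mean of the
#' five ROI means (a percentage is used because DBT pixel scales are not
#' normalized across vendors; the denominator convention is recorded in
#' the result).
#'
#' @param volume a \code{recon_volume}.
#' @param geometry a \code{phantom_geometry}.
#' @param pose a \code{pose_estimate} or \code{NULL}.
#' @param slice_index slice to measure (default: the test-plane slice).
#' @param rois optional data.frame overriding the five ROIs.
#' @return List: \code{percent} (the metric), \code{roi_means},
#'   \code{roi_stats} (data.frame), \code{denominator}
#'   (\code{"grand_mean_of_roi_means"}), \code{slice}.
#' @export
global_uniformity <- function(volume, geometry, pose = NULL,
                              slice_index = NULL, rois = NULL) {
  rois <- rois %||% default_rois(geometry)$global_rois
  if (nrow(rois) < 2) stopf("need >= 2 ROIs")
  check_rois_clear(rois, geometry)
  slice_index <- slice_index %||%
    world_to_slice(volume, geometry$test_plane_z, clamp = TRUE)
  zs <- vol_z(volume)
  stats_l <- lapply(seq_len(nrow(rois)), function(i) {
    ctr <- roi_center_posed(rois$x[i], rois$y[i], zs[slice_index], pose)
    disc_stats(volume, slice_index, ctr[1], ctr[2], rois$radius[i])
  })
  mns <- vapply(stats_l, function(s) s$mean, numeric(1))
  grand <- mean(mns)
  if (grand == 0) stopf("grand mean of ROI means is zero")
  pct <- 100 * (max(mns) - min(mns)) / grand
  list(percent = pct, roi_means = stats::setNames(mns, rois$id),
       roi_stats = data.frame(roi = rois$id, mean = mns,
                              sd = vapply(stats_l, function(s) s$sd,
                                          numeric(1)),
                              n_pixels = vapply(stats_l, function(s) s$n,
                                                numeric(1))),
       denominator = "grand_mean_of_roi_means", slice = slice_index)
}

#' Signal-to-noise ratio
#'
#' Net signal over a uniform ROI divided by the noise SD measured in a
#' neighboring ROI. "Net" uses a zero offset on the raw pixel scale (no
#' portable DBT unit scale exists); a vendor-specific offset can be
#' supplied.
#'
#' @param volume a \code{recon_volume}.
#' @param geometry a \code{phantom_geometry}.
#' @param pose a \code{pose_estimate} or \code{NULL}.
#' @param slice_index slice to measure (default: test-plane slice).
#' @param offset signal offset convention (default 0, recorded in the
#'   result).
#' @param rois optional 2-row data.frame (signal ROI, noise ROI).
#' @return List: \code{snr}, \code{signal_mean}, \code{noise_sd},
#'   \code{offset}, \code{degenerate} (TRUE with \code{snr = Inf} when the
#'   noise SD is zero, e.g. a noiseless synthetic volume).
#' @export
snr <- function(volume, geometry, pose = NULL, slice_index = NULL,
                offset = 0, rois = NULL) {
  rois <- rois %||% default_rois(geometry)$snr
  check_rois_clear(rois, geometry)
  slice_index <- slice_index %||%
    world_to_slice(volume, geometry$test_plane_z, clamp = TRUE)
  zs <- vol_z(volume)
  ctr_s <- roi_center_posed(rois$x[1], rois$y[1], zs[slice_index], pose)
  ctr_n <- roi_center_posed(rois$x[2], rois$y[2], zs[slice_index], pose)
  sig <- disc_stats(volume, slice_index, ctr_s[1], ctr_s[2], rois$radius[1])
  noi <- disc_stats(volume, slice_index, ctr_n[1], ctr_n[2], rois$radius[2])
  degenerate <- !is.finite(noi$sd) || noi$sd == 0
  list(snr = if (degenerate) Inf else (sig$mean - offset) / noi$sd,
       signal_mean = sig$mean, noise_sd = noi$sd, offset = offset,
       degenerate = degenerate, slice = slice_index)
}

#' Contrast-to-noise ratio over the aluminum square
#'
#' Net signal (mean inside the square, inset from its edges, minus the
#' mean of an adjacent background ROI) divided by the background noise SD,
#' on the square's in-focus slice. Noise is measured in the background ROI
#' rather than inside the square, avoiding any contrast-dependent noise.
#'
#' @param volume a \code{recon_volume}.
#' @param geometry a \code{phantom_geometry}.
#' @param pose a \code{pose_estimate} or \code{NULL}.
#' @param inset_mm inset of the square ROI from the square edges
#'   (default 2).
#' @param background_roi optional 1-row data.frame (x, y, radius).
#' @return List: \code{cnr}, \code{al_mean}, \code{bg_mean}, \code{bg_sd},
#'   \code{degenerate} flag (zero noise), \code{slice}.
#' @export
cnr <- function(volume, geometry, pose = NULL, inset_mm = 2,
                background_roi = NULL) {
  sq <- geometry$al_square
  bg_roi <- background_roi %||% default_rois(geometry)$cnr_background
  check_rois_clear(bg_roi, geometry)
  s <- world_to_slice(volume, sq$center[["z"]])
  if (is.na(s)) stopf("aluminum square slice not inside the volume")
  ctr <- roi_center_posed(sq$center[["x"]], sq$center[["y"]],
                          sq$center[["z"]], pose)
  r_in <- sq$side / 2 - inset_mm
  if (r_in <= 0) stopf("inset leaves no pixels inside the aluminum square")
  al <- disc_stats(volume, s, ctr[1], ctr[2], r_in)
  if (al$n == 0) stopf("aluminum square not located in the field")
  zb <- vol_z(volume)[s]
  bctr <- roi_center_posed(bg_roi$x[1], bg_roi$y[1], zb, pose)
  bg <- disc_stats(volume, s, bctr[1], bctr[2], bg_roi$radius[1])
  degenerate <- !is.finite(bg$sd) || bg$sd == 0
  list(cnr = if (degenerate) Inf else (al$mean - bg$mean) / bg$sd,
       al_mean = al$mean, bg_mean = bg$mean, bg_sd = bg$sd,
       degenerate = degenerate, slice = s)
}

#' Fit the noise-versus-mAs power law
#'
#' Least squares of log(SD) on log(mAs): SD = a * mAs^b. Exposure noise in
#' quantum-limited imaging gives b near -0.5 (the square-root dependence).
#'
#' @param points data.frame with columns \code{mas} and \code{sd}, one row
#'   per exposure (>= 3 distinct positive mAs values).
#' @return An object of class \code{noise_fit}: \code{a}, \code{b},
#'   \code{residual} (RMS of log-scale residuals), \code{points}.
#' @export
fit_noise_vs_mas <- function(points) {
  if (!all(c("mas", "sd") %in% names(points)))
    stopf("points needs columns 'mas' and 'sd'")
  if (any(points$mas <= 0) || any(points$sd <= 0))
    stopf("mAs and SD values must be positive")
  if (length(unique(points$mas)) < 3)
    stopf("need >= 3 distinct mAs values")
  fit <- stats::lm(log(sd) ~ log(mas), data = points)
  co <- stats::coef(fit)
  out <- list(a = unname(exp(co[1])), b = unname(co[2]),
              residual = sqrt(mean(stats::residuals(fit)^2)),
              points = points)
  class(out) <- "noise_fit"
  out
}

#' @export
print.noise_fit <- function(x, ...) {
  cat(sprintf("noise power law: SD = %.4g * mAs^%.4g (RMS log residual %.3g, %d points)\n",
              x$a, x$b, x$residual, nrow(x$points)))
  invisible(x)
}

#' @export
coef.noise_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.noise_fit <- function(object, mas, ...) object$a * mas^object$b

#' Noise SD measured in the SNR noise ROI of a volume
#'
#' Convenience used for mAs sweeps: the SD of the pixel values in the
#' default noise ROI on the test-plane slice.
#'
#' @inheritParams snr
#' @export
measure_noise_sd <- function(volume, geometry, pose = NULL,
                             slice_index = NULL) {
  snr(volume, geometry, pose = pose, slice_index = slice_index)$noise_sd
}

#' Export per-slice uniformity trends as CSV
#' @param df result of \code{\link{regional_uniformity}}.
#' @param path output CSV path.
#' @export
write_uniformity_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
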