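# Low-contrast sphere conspicuity and the contrast-detail noise model:
# the SD of the means of circles matching each sphere diameter, sampled
# from the uniform region next to the spheres, falls off as k/diameter
# (fewer pixels per circle means a noisier mean).

#' Score the low-contrast spheres
#'
#' Per sphere: a disc ROI of the sphere's diameter at its (pose-corrected)
#' center on the in-focus slice, a local background annulus around it, the
#' net signal and local CNR, and a detected flag (local CNR at or above
#' the threshold). Detection here is threshold-based on local CNR --
#' observer and ROC models are deliberately out of scope.
#'
#' @param volume a \code{recon_volume}.
#' @param geometry a \code{phantom_geometry}.
#' @param pose a \code{pose_estimate} or \code{NULL}.
#' @param cnr_threshold detection threshold on local CNR (default 1.0).
#' @param annulus_gap_mm gap between sphere edge and annulus (default 1).
#' @param annulus_width_mm annulus width (default 2).
#' @return data.frame with one row per sphere: diameter, net_signal,
#'   cnr_local, detected, bg_mean, bg_sd.
#' @export
score_spheres <- function(volume, geometry, pose = NULL, cnr_threshold = 1.0,
                          annulus_gap_mm = 1, annulus_width_mm = 2) {
  sp <- geometry$low_contrast_spheres
  xs <- vol_x(volume); ys <- vol_y(volume)
  out <- list()
  for (i in seq_len(nrow(sp))) {
    ctr <- pose_point(sp$x[i], sp$y[i], sp$z[i], pose)
    s <- world_to_slice(volume, ctr[3])
    if (is.na(s)) stopf("sphere (d = %g mm) center out of field",
                        sp$diameter[i])
    r <- sp$diameter[i] / 2
    r_out1 <- r + annulus_gap_mm
    r_out2 <- r_out1 + annulus_width_mm
    ci <- which(abs(xs - ctr[1]) <= r_out2)
    ri <- which(abs(ys - ctr[2]) <= r_out2)
    if (!length(ci) || !length(ri))
      stopf("sphere (d = %g mm) center out of field", sp$diameter[i])
    sub <- matrix(volume$data[s, ri, ci], length(ri), length(ci))
    d2 <- outer((ys[ri] - ctr[2])^2, (xs[ci] - ctr[1])^2, "+")
    in_disc <- d2 <= r^2
    in_ann <- d2 > r_out1^2 & d2 <= r_out2^2
    if (!any(in_disc) || !any(in_ann))
      stopf("sphere (d = %g mm): empty ROI or annulus", sp$diameter[i])
    bg_mean <- mean(sub[in_ann]); bg_sd <- stats::sd(sub[in_ann])
    net <- mean(sub[in_disc]) - bg_mean
    cnr_l <- if (!is.finite(bg_sd) || bg_sd == 0) {
      if (net > 0) Inf else 0
    } else net / bg_sd
    out[[length(out) + 1L]] <- data.frame(
      diameter = sp$diameter[i], net_signal = net, cnr_local = cnr_l,
      detected = cnr_l >= cnr_threshold, bg_mean = bg_mean, bg_sd = bg_sd)
  }
  df <- do.call(rbind, out)
  df[order(df$diameter), ]
}

#' Default contrast-detail sampling region
#'
#' Rectangle (phantom coordinates, mm) in the uniform area next to the
#' low-contrast spheres, clear of every test object by 2 mm.
#'
#' @param geometry a \code{phantom_geometry}.
#' @return list(xmin, xmax, ymin, ymax).
#' @export
cd_sampling_region <- function(geometry) {
  list(xmin = 21, xmax = 46, ymin = 29, ymax = 66)
}

# deterministic hex packing of non-overlapping circle centers inside a
# rectangle, circle diameter d plus a small guard gap
hex_pack_centers <- function(region, d, gap = 0.2) {
  pitch <- d + gap
  r <- d / 2
  xseq0 <- seq(region$xmin + r, region$xmax - r, by = pitch)
  yseq <- seq(region$ymin + r, region$ymax - r, by = pitch * sqrt(3) / 2)
  if (!length(xseq0) || !length(yseq))
    return(data.frame(x = numeric(0), y = numeric(0)))
  out <- list()
  for (j in seq_along(yseq)) {
    xo <- if (j %% 2 == 0) pitch / 2 else 0
    xr <- xseq0 + xo
    xr <- xr[xr + r <= region$xmax + 1e-9]
    if (length(xr))
      out[[length(out) + 1L]] <- data.frame(x = xr, y = yseq[j])
  }
  do.call(rbind, out)
}

#' SD of circle means sampled from a uniform region
#'
#' Places non-overlapping circles of the given diameter on a deterministic
#' hexagonal packing inside the region, takes the mean pixel value of
#' each, and returns the standard deviation of those means. This is the
#' noise datum of the contrast-detail model: smaller circles average fewer
#' pixels, so their means scatter more.
#'
#' @param slice 2D matrix of pixel values (row = y, col = x).
#' @param diameter_mm circle diameter in mm.
#' @param spacing_mm pixel spacing of \code{slice}.
#' @param region list(xmin, xmax, ymin, ymax) in mm relative to the slice
#'   grid (pixel centers at spacing/2, 3*spacing/2, ...).
#' @param n_samples circles to use; capped by how many non-overlapping
#'   circles fit (error if fewer than \code{min_samples} fit).
#' @param min_samples minimum acceptable number of circles (default 6; the
#'   largest diameters pack only a handful of circles into the uniform
#'   region).
#' @return list: \code{sd_of_means}, \code{n} (circles used),
#'   \code{means}, \code{centers}.
#' @export
sample_circle_means <- function(slice, diameter_mm, spacing_mm,
                                region = NULL, n_samples = 50,
                                min_samples = 6) {
  stopifnot(is.matrix(slice), diameter_mm > 0, spacing_mm > 0)
  region <- region %||% list(xmin = 0, xmax = ncol(slice) * spacing_mm,
                             ymin = 0, ymax = nrow(slice) * spacing_mm)
  centers <- hex_pack_centers(region, diameter_mm)
  if (nrow(centers) < min_samples)
    stopf("only %d non-overlapping circles of %g mm fit in the region (need >= %d)",
          nrow(centers), diameter_mm, min_samples)
  if (nrow(centers) > n_samples) centers <- centers[seq_len(n_samples), ]
  xs <- (seq_len(ncol(slice)) - 0.5) * spacing_mm
  ys <- (seq_len(nrow(slice)) - 0.5) * spacing_mm
  r <- diameter_mm / 2
  means <- vapply(seq_len(nrow(centers)), function(i) {
    ci <- which(abs(xs - centers$x[i]) <= r)
    ri <- which(abs(ys - centers$y[i]) <= r)
    sub <- slice[ri, ci, drop = FALSE]
    msk <- outer((ys[ri] - centers$y[i])^2, (xs[ci] - centers$x[i])^2,
                 "+") <= r^2
    mean(sub[msk])
  }, numeric(1))
  list(sd_of_means = stats::sd(means), n = nrow(centers), means = means,
       centers = centers)
}

#' Contrast-detail circle-mean SDs for a volume
#'
#' Runs \code{\link{sample_circle_means}} on the sphere-plane slice over
#' the default diameters (the sphere set from 1 mm up, largest first),
#' sampling from the uniform region next to the spheres. The region is
#' checked geometrically against every (dilated) object footprint.
#'
#' @param volume a \code{recon_volume}.
#' @param geometry a \code{phantom_geometry}.
#' @param pose a \code{pose_estimate} or \code{NULL} (the sampling region
#'   is pose-corrected through its corner points).
#' @param diameters circle diameters in mm (default: 10, 8, 6, 4, 3, 2,
#'   1.5, 1 -- the sphere diameters down to 1 mm).
#' @param n_samples target circles per diameter (default 50; smaller
#'   diameters reach it, larger ones are capped by packing).
#' @return data.frame with columns diameter and sd_of_means (plus
#'   n_circles); suitable for \code{\link{fit_cd_model}}.
#' @export
cd_noise_data <- function(volume, geometry, pose = NULL,
                          diameters = c(10, 8, 6, 4, 3, 2, 1.5, 1),
                          n_samples = 50) {
  region <- cd_sampling_region(geometry)
  # geometric exclusion check on the region corners/edges
  fps <- object_footprints(geometry)
  for (i in seq_len(nrow(fps))) {
    fp <- fps[i, ]
    rx <- fp$rx + 2; ry <- fp$ry + 2
    if (fp$x + rx > region$xmin && fp$x - rx < region$xmax &&
        fp$y + ry > region$ymin && fp$y - ry < region$ymax)
      stopf("contrast-detail region overlaps object '%s'", fp$label)
  }
  s <- world_to_slice(volume,
                      pose_point(mean(c(region$xmin, region$xmax)),
                                 mean(c(region$ymin, region$ymax)),
                                 geometry$low_contrast_spheres$z[1],
                                 pose)[3], clamp = TRUE)
  sl <- vol_slice(volume, s)
  # express the region in the slice's own pixel frame
  ctr <- pose_point(mean(c(region$xmin, region$xmax)),
                    mean(c(region$ymin, region$ymax)),
                    geometry$low_contrast_spheres$z[1], pose)
  halfx <- (region$xmax - region$xmin) / 2
  halfy <- (region$ymax - region$ymin) / 2
  reg_px <- list(xmin = ctr[1] - halfx - vol_x(volume)[1] +
                   volume$spacing[["dx"]] / 2,
                 xmax = ctr[1] + halfx - vol_x(volume)[1] +
                   volume$spacing[["dx"]] / 2,
                 ymin = ctr[2] - halfy - vol_y(volume)[1] +
                   volume$spacing[["dy"]] / 2,
                 ymax = ctr[2] + halfy - vol_y(volume)[1] +
                   volume$spacing[["dy"]] / 2)
  out <- lapply(diameters, function(d) {
    res <- sample_circle_means(sl, d, volume$spacing[["dx"]],
                               region = reg_px, n_samples = n_samples)
    data.frame(diameter = d, sd_of_means = res$sd_of_means,
               n_circles = res$n)
  })
  do.call(rbind, out)
}

#' Fit the hyperbolic contrast-detail noise model
#'
#' Single-parameter least squares of SD against k / diameter. For white
#' noise the SD of a circle mean scales as 1/diameter (pixel count grows
#' as diameter squared), which is the hyperbolic relation observed in
#' contrast-detail analyses.
#'
#' @param points data.frame with columns \code{diameter} and
#'   \code{sd_of_means} (>= 4 positive diameters).
#' @return An object of class \code{cd_model}: \code{k},
#'   \code{residual_rms}, \code{residual_relative} (RMS residual over the
#'   mean SD -- large values flag data that do not follow k/d),
#'   \code{points} (with fitted values).
#' @export
fit_cd_model <- function(points) {
  if (!all(c("diameter", "sd_of_means") %in% names(points)))
    stopf("points needs columns 'diameter' and 'sd_of_means'")
  if (any(points$diameter <= 0)) stopf("diameters must be positive")
  if (nrow(points) < 4) stopf("need >= 4 diameters")
  x <- 1 / points$diameter
  y <- points$sd_of_means
  k <- sum(x * y) / sum(x * x)
  fitted <- k * x
  res <- y - fitted
  out <- list(k = k, residual_rms = sqrt(mean(res^2)),
              residual_relative = sqrt(mean(res^2)) / mean(y),
              points = cbind(points, model_sd = fitted))
  class(out) <- "cd_model"
  out
}

#' @export
print.cd_model <- function(x, ...) {
  cat(sprintf("contrast-detail model: SD(d) = %.4g / d; RMS residual %.3g (%.1f%% of mean SD)%s\n",
              x$k, x$residual_rms, 100 * x$residual_relative,
              if (x$residual_relative > 0.25) " [poor fit]" else ""))
  invisible(x)
}

#' @export
coef.cd_model <- function(object, ...) c(k = object$k)

#' Export contrast-detail data as CSV
#' @param model a \code{cd_model}.
#' @param path output CSV path.
#' @export
write_cd_csv <- function(model, path) {
  utils::write.csv(model$points, path, row.names = FALSE)
  invisible(path)
}
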