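# Slice geometry: slice sensitivity profiles (SSP) sampled by the folded
# bead ramps via trigonometric projection of z depth onto the image plane,
# slice width as SSP FWHM, slice incrementation from consecutive SSP peak
# positions, z-axis geometry from the 5 mm aluminum beads, and artifact
# spread functions.

#' Extract a slice sensitivity profile from a bead ramp
#'
#' For each bead of the (pose-corrected) ramp, the maximum intensity over
#' the rows containing the ramp is extracted at the bead's column; each
#' peak is mapped to the bead's known z, giving the SSP sampled at the
#' bead's vertical spacing. The local background -- the same max-over-rows
#' statistic taken in an object-free strip beside the ramp, so the maximum
#' statistic's noise bias cancels -- is subtracted, a smoothing spline is
#' fitted through the peak values, and the curve is normalized to peak 1.
#'
#' @param volume a \code{recon_volume}.
#' @param ramp a \code{bead_ramp}.
#' @param slice_index reconstructed slice to sample (default: the slice
#'   nearest the ramp's mid-rise z).
#' @param pose a \code{pose_estimate} or \code{NULL}.
#' @param row_halfwidth half-height in mm of the row band searched around
#'   each bead (default 0.3).
#' @param col_halfwidth half-width in mm of the column band around each
#'   bead (default 0.2).
#' @param bg_offset_mm y offset of the background strip from the lower
#'   limb (default -4, toward the chest wall where no objects sit).
#' @param spar optional smoothing parameter passed to
#'   \code{\link[stats]{smooth.spline}}; by default the smoothing is tied
#'   to the noise SD estimated from the background strip (the spar whose
#'   residual RMS matches \code{smooth_factor} times that SD).
#' @param smooth_factor fraction of the estimated noise SD targeted by the
#'   residual RMS of the smoothing spline; by default scaled with the
#'   relative noise level (low-noise curves are tracked closely, noisy
#'   ones smoothed harder), between 0.5 and 0.85.
#' @return An object of class \code{ssp_curve}: \code{z} (fine grid, mm),
#'   \code{sensitivity} (peak-normalized), \code{fwhm} (mm),
#'   \code{samples} (per-bead z and raw normalized values), and
#'   \code{source} (ramp side and slice index).
#' @export
extract_ssp <- function(volume, ramp, slice_index = NULL, pose = NULL,
                        row_halfwidth = 0.3, col_halfwidth = 0.2,
                        bg_offset_mm = -4, spar = NULL,
                        smooth_factor = NULL) {
  stopifnot(inherits(ramp, "bead_ramp"))
  bp <- bead_positions(ramp)
  pc <- pose_apply(bp, pose)
  xs <- vol_x(volume); ys <- vol_y(volume); zs <- vol_z(volume)
  if (is.null(slice_index)) {
    zmid <- mean(range(bp$z))
    slice_index <- world_to_slice(volume, pose_point(mean(range(bp$x)),
                                                     mean(bp$y), zmid,
                                                     pose)[3], clamp = TRUE)
  }
  sl <- vol_slice(volume, slice_index)

  # per bead: average the small column band (the blurred bead spans it),
  # lightly smooth the row profile, then take the max over the rows
  # containing the ramp. The smoothing keeps the max statistic's noise
  # bias nearly level-independent, so the background-strip subtraction
  # cancels it instead of distorting the profile shape.
  peak_at <- function(px, py) {
    ci <- which(abs(xs - px) <= col_halfwidth)
    ri <- which(abs(ys - py) <= row_halfwidth)
    if (!length(ci) || !length(ri)) return(NA_real_)
    prof <- rowMeans(sl[ri, ci, drop = FALSE])
    if (length(prof) >= 3) {
      sm <- stats::filter(prof, rep(1 / 3, 3))
      prof <- sm[!is.na(sm)]
    }
    max(prof)
  }
  vals <- mapply(peak_at, pc[, "x"], pc[, "y"])
  bgs <- mapply(peak_at, pc[, "x"], pc[, "y"] + bg_offset_mm)
  bg <- stats::median(bgs, na.rm = TRUE)
  ok <- !is.na(vals)
  if (sum(ok) < 5)
    stopf("fewer than 5 resolvable ramp peaks in the field (%d)", sum(ok))

  z <- bp$z[ok]
  s <- vals[ok] - bg
  ord <- order(z)
  z <- z[ord]; s <- s[ord]

  # smoothing tied to the estimated noise SD (discrepancy principle): pick
  # the spar whose residual RMS matches a fraction of the noise measured
  # in the background strip. GCV alone chases noise bumps near the peak at
  # low amplitude, inflating the normalization and narrowing the width;
  # matching the full noise SD instead rounds off sharply peaked profiles.
  # The fraction therefore scales with the relative noise level.
  sigma_raw <- stats::mad(bgs[!is.na(bgs)])
  if (is.null(smooth_factor)) {
    sigma_rel <- sigma_raw / max(s)
    smooth_factor <- min(0.85, max(0.5, 0.5 + 6 * sigma_rel))
  }
  sigma_hat <- smooth_factor * sigma_raw
  fit <- if (!is.null(spar)) {
    stats::smooth.spline(z, s, spar = spar)
  } else if (!is.finite(sigma_hat) || sigma_hat < 1e-8) {
    stats::smooth.spline(z, s)
  } else {
    rms_at <- function(sp) {
      f <- stats::smooth.spline(z, s, spar = sp)
      sqrt(mean((s - stats::predict(f, z)$y)^2))
    }
    lo <- -0.5; hi <- 1.5
    if (rms_at(lo) >= sigma_hat) sp_use <- lo
    else if (rms_at(hi) <= sigma_hat) sp_use <- hi
    else {
      for (i in 1:20) {
        mid <- (lo + hi) / 2
        if (rms_at(mid) < sigma_hat) lo <- mid else hi <- mid
      }
      sp_use <- (lo + hi) / 2
    }
    stats::smooth.spline(z, s, spar = sp_use)
  }
  zf <- seq(min(z), max(z), by = 0.01)
  sf <- stats::predict(fit, zf)$y
  pk <- max(sf)
  if (pk <= 0) stopf("SSP has no positive peak on slice %d", slice_index)

  out <- list(z = zf, sensitivity = sf / pk,
              samples = data.frame(z = z, value = s / pk),
              source = list(side = ramp$side, slice = slice_index,
                            background = bg))
  class(out) <- "ssp_curve"
  out$fwhm <- tryCatch(fwhm(out), error = function(e) NA_real_)
  out
}

#' Full width at half maximum of a sampled curve
#'
#' Linear interpolation of the half-maximum crossings on each side of the
#' peak of a normalized single-peaked curve.
#'
#' @param curve an \code{ssp_curve} (or any list with \code{z} and
#'   \code{sensitivity}).
#' @return Width in mm (right crossing minus left crossing).
#' @export
fwhm <- function(curve) {
  hc <- half_crossings(curve$z, curve$sensitivity)
  if (any(is.na(hc)))
    stopf("no half-maximum crossing on the %s side (truncated profile)",
          paste(names(hc)[is.na(hc)], collapse = " and "))
  unname(hc["right"] - hc["left"])
}

#' @export
print.ssp_curve <- function(x, ...) {
  cat(sprintf("SSP (%s ramp, slice %d): FWHM %.3f mm, %d bead samples\n",
              x$source$side, x$source$slice,
              if (is.na(x$fwhm)) NA else x$fwhm, nrow(x$samples)))
  invisible(x)
}

#' @export
plot.ssp_curve <- function(x, ...) {
  graphics::plot(x$samples$z, x$samples$value, xlab = "z (mm)",
                 ylab = "normalized sensitivity",
                 main = sprintf("SSP, %s ramp (FWHM %.2f mm)",
                                x$source$side, x$fwhm), ...)
  graphics::lines(x$z, x$sensitivity, col = "steelblue", lwd = 2)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Headline slice width of a volume
#'
#' Mean SSP FWHM over replicate profiles: both folded ramp sets, each
#' sampled on a few contiguous slices around the ramp mid-rise (SSPs from
#' nominally contiguous slices agree closely, so they serve as replicate
#' estimates of the same slice width).
#'
#' @inheritParams extract_ssp
#' @param geometry a \code{phantom_geometry}.
#' @param n_slices contiguous slices per ramp (default 3).
#' @return List: \code{fwhm_mm} (mean over replicates), \code{per_curve}
#'   (data.frame of ramp, slice, fwhm), \code{n}.
#' @export
slice_width <- function(volume, geometry, pose = NULL, n_slices = 3,
                        spar = NULL) {
  rows <- list()
  for (r in geometry$ramps) {
    bp <- bead_positions(r)
    zmid <- mean(range(bp$z))
    s0 <- world_to_slice(volume, pose_point(mean(range(bp$x)), mean(bp$y),
                                            zmid, pose)[3], clamp = TRUE)
    half <- (n_slices - 1) %/% 2
    for (s in (s0 - half):(s0 - half + n_slices - 1)) {
      if (s < 1 || s > dim(volume$data)[1]) next
      f <- tryCatch(extract_ssp(volume, r, slice_index = s, pose = pose,
                                spar = spar)$fwhm,
                    error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(ramp = r$side, slice = s,
                                              fwhm = f)
    }
  }
  df <- do.call(rbind, rows)
  ok <- is.finite(df$fwhm)
  if (!any(ok)) stopf("no usable SSP replicate for slice width")
  list(fwhm_mm = mean(df$fwhm[ok]), per_curve = df, n = sum(ok))
}

#' Slice incrementation from consecutive SSP peak positions
#'
#' Extracts SSPs on consecutive reconstructed slices around the ramp's
#' mid-rise and reports the mean difference of their peak z positions,
#' which measures the actual spacing between reconstructed slices.
#'
#' @inheritParams extract_ssp
#' @param n_slices number of consecutive slices to use (default 5).
#' @return List: \code{increment_mm} (mean peak-to-peak spacing),
#'   \code{peak_z} (per-slice SSP peak positions), \code{slices},
#'   \code{outliers} (slice pairs whose spacing deviates from the median
#'   by more than half the median, e.g. duplicated slices).
#' @export
slice_incrementation <- function(volume, ramp, pose = NULL, n_slices = 5,
                                 spar = NULL) {
  if (n_slices < 3) stopf("need >= 3 consecutive slices")
  bp <- bead_positions(ramp)
  zmid <- mean(range(bp$z))
  s0 <- world_to_slice(volume, zmid, clamp = TRUE)
  half <- (n_slices - 1) %/% 2
  slices <- (s0 - half):(s0 - half + n_slices - 1)
  slices <- slices[slices >= 1 & slices <= dim(volume$data)[1]]
  if (length(slices) < 3) stopf("need >= 3 consecutive slices in the field")
  peak_z <- vapply(slices, function(s) {
    cv <- extract_ssp(volume, ramp, slice_index = s, pose = pose, spar = spar)
    cv$z[which.max(cv$sensitivity)]
  }, numeric(1))
  d <- diff(peak_z)
  med <- stats::median(abs(d))
  outliers <- which(abs(abs(d) - med) > 0.5 * med)
  list(increment_mm = mean(abs(d)), peak_z = peak_z, slices = slices,
       outliers = outliers)
}

#' z extent covered by a folded bead-ramp set
#'
#' Scans every reconstructed slice for each ramp bead's in-plane peak,
#' flags the beads that appear anywhere in the volume, and maps them to z
#' via the geometry; the difference between the largest and smallest
#' detected z is the z range the folded set samples (the full rise when
#' the whole ramp is imaged).
#'
#' @inheritParams extract_ssp
#' @param detect_frac detection threshold as a fraction of the strongest
#'   bead response above background (default 0.1).
#' @return List: \code{z_extent_mm}, \code{n_detected}, \code{detected}
#'   (logical per bead), \code{response} (per-bead through-slice maximum).
#' @export
ramp_z_extent <- function(volume, ramp, pose = NULL, row_halfwidth = 0.3,
                          col_halfwidth = 0.2, bg_offset_mm = -4,
                          detect_frac = 0.1) {
  bp <- bead_positions(ramp)
  pc <- pose_apply(bp, pose)
  xs <- vol_x(volume); ys <- vol_y(volume)
  nsl <- dim(volume$data)[1]
  best <- rep(-Inf, nrow(bp))
  bg_best <- rep(-Inf, nrow(bp))
  for (s in seq_len(nsl)) {
    sl <- vol_slice(volume, s)
    for (i in seq_len(nrow(bp))) {
      ci <- which(abs(xs - pc[i, "x"]) <= col_halfwidth)
      ri <- which(abs(ys - pc[i, "y"]) <= row_halfwidth)
      if (!length(ci) || !length(ri)) next
      best[i] <- max(best[i], max(sl[ri, ci]))
      bri <- which(abs(ys - (pc[i, "y"] + bg_offset_mm)) <= row_halfwidth)
      if (length(bri)) bg_best[i] <- max(bg_best[i], max(sl[bri, ci]))
    }
  }
  bg <- stats::median(bg_best[is.finite(bg_best)])
  resp <- best - bg
  if (!any(is.finite(resp)) || max(resp, na.rm = TRUE) <= 0)
    stopf("no ramp beads detected in the volume")
  detected <- is.finite(resp) & resp > detect_frac * max(resp, na.rm = TRUE)
  if (!any(detected)) stopf("no ramp beads detected in the volume")
  list(z_extent_mm = diff(range(bp$z[detected])),
       n_detected = sum(detected), detected = detected, response = resp)
}

#' z-axis geometry from the 5 mm aluminum beads
#'
#' For each bead, the through-slice intensity profile (per-slice maximum in
#' a bead-centered ROI) is fitted with a smoothing spline and its peak z
#' located; the consecutive differences of the peak positions measure the
#' z spacing of the beads (nominally 10 mm apart).
#'
#' @param volume a \code{recon_volume}.
#' @param geometry a \code{phantom_geometry}.
#' @param pose a \code{pose_estimate} or \code{NULL}.
#' @param roi_mm in-plane half-width of the per-bead ROI (default 4).
#' @return List: \code{spacings_mm} (consecutive peak-z differences, beads
#'   ordered by z), \code{peak_z}, \code{profiles} (per-bead data.frames of
#'   slice z and response).
#' @export
z_bead_spacing <- function(volume, geometry, pose = NULL, roi_mm = 4) {
  zb <- geometry$z_beads[order(geometry$z_beads$z), ]
  pc <- pose_apply(zb, pose)
  xs <- vol_x(volume); ys <- vol_y(volume); zs <- vol_z(volume)
  peak_z <- numeric(nrow(zb))
  profiles <- vector("list", nrow(zb))
  for (i in seq_len(nrow(zb))) {
    ci <- which(abs(xs - pc[i, "x"]) <= roi_mm)
    ri <- which(abs(ys - pc[i, "y"]) <= roi_mm)
    if (!length(ci) || !length(ri))
      stopf("z bead %d not inside the volume field", i)
    resp <- vapply(seq_along(zs), function(s)
      max(volume$data[s, ri, ci]), numeric(1))
    # the peak must stand clearly above the profile's own scatter
    base <- stats::median(resp)
    spread <- stats::mad(resp)
    if (max(resp) <= base + max(6 * spread, 1e-9))
      stopf("z bead %d not found (no through-slice peak)", i)
    # fit around the dominant peak only
    ipk <- which.max(resp)
    span <- which(abs(zs - zs[ipk]) <= zb$diameter[i] + 4)
    if (length(span) >= 4) {
      fit <- stats::smooth.spline(zs[span], resp[span],
                                  df = min(6, length(span) - 1))
      zf <- seq(min(zs[span]), max(zs[span]), by = 0.01)
      sf <- stats::predict(fit, zf)$y
      peak_z[i] <- zf[which.max(sf)]
    } else {
      peak_z[i] <- zs[ipk]
    }
    profiles[[i]] <- data.frame(z = zs[span], response = resp[span])
  }
  list(spacings_mm = diff(peak_z), peak_z = peak_z, profiles = profiles)
}

#' Artifact spread function of a high-contrast bead
#'
#' Profiles through the (pose-corrected) bead center along x and y, on the
#' bead's in-focus slice by default or at a chosen slice offset, normalized
#' to peak 1. Reported as a pair of curves, ASF(x) and ASF(y).
#'
#' @param volume a \code{recon_volume}.
#' @param geometry a \code{phantom_geometry}.
#' @param bead_index which z bead to use (default 2, the central one).
#' @param pose a \code{pose_estimate} or \code{NULL}.
#' @param slice_offset signed slice offset from the in-focus slice
#'   (default 0).
#' @param extent_mm profile half-extent in mm (default 8).
#' @return List of two objects of class \code{asf_curve} (elements
#'   \code{x} and \code{y}), each with \code{offset} (mm, symmetric about
#'   0), \code{response} (normalized), \code{axis} and \code{bead}.
#' @export
asf <- function(volume, geometry, bead_index = 2L, pose = NULL,
                slice_offset = 0L, extent_mm = 8) {
  zb <- geometry$z_beads
  if (bead_index < 1 || bead_index > nrow(zb)) stopf("no such z bead")
  pc <- pose_apply(zb[bead_index, , drop = FALSE], pose)
  xs <- vol_x(volume); ys <- vol_y(volume)
  s0 <- world_to_slice(volume, pc[1, "z"])
  if (is.na(s0)) stopf("z bead %d not inside the volume field", bead_index)
  s <- s0 + slice_offset
  if (s < 1 || s > dim(volume$data)[1])
    stopf("slice offset %d falls outside the volume", slice_offset)
  sl <- vol_slice(volume, s)
  r0 <- world_to_row(volume, pc[1, "y"], clamp = TRUE)
  c0 <- world_to_col(volume, pc[1, "x"], clamp = TRUE)
  ci <- which(abs(xs - pc[1, "x"]) <= extent_mm)
  ri <- which(abs(ys - pc[1, "y"]) <= extent_mm)
  bg <- stats::median(sl[ri, ci])
  if (max(sl[ri, ci]) <= bg + max(6 * stats::mad(sl[ri, ci]), 1e-9))
    stopf("z bead %d not found for ASF (no in-plane peak)", bead_index)

  mk_curve <- function(offset, response, axis) {
    response <- response - bg
    pk <- max(response)
    if (pk <= 0) stopf("ASF has no positive peak")
    out <- list(offset = offset, response = response / pk, axis = axis,
                bead = bead_index, slice = s, slice_offset = slice_offset)
    class(out) <- "asf_curve"
    out
  }
  list(x = mk_curve(xs[ci] - pc[1, "x"], sl[r0, ci], "x"),
       y = mk_curve(ys[ri] - pc[1, "y"], sl[ri, c0], "y"))
}

#' @export
print.asf_curve <- function(x, ...) {
  hw <- tryCatch(fwhm(list(z = x$offset, sensitivity = x$response)),
                 error = function(e) NA_real_)
  cat(sprintf("ASF(%s), bead %d, slice offset %d: FWHM %.3f mm\n",
              x$axis, x$bead, x$slice_offset, hw))
  invisible(x)
}

#' Export an SSP or ASF curve as CSV
#' @param curve an \code{ssp_curve} or \code{asf_curve}.
#' @param path output CSV path.
#' @export
write_curve_csv <- function(curve, path) {
  df <- if (inherits(curve, "ssp_curve"))
    data.frame(z_mm = curve$z, sensitivity = curve$sensitivity)
  else data.frame(offset_mm = curve$offset, response = curve$response)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
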