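# Chest-wall offset (missing tissue): the four stair-step gauges rise into
# the phantom from the chest wall in fixed increments; counting how many
# steps are visible in the reconstruction measures how much tissue depth
# adjacent to the wall is missing from the image.

#' Missing tissue from a visible gauge extent
#'
#' @param visible_extent visible gauge extent in mm.
#' @param gauge a \code{step_gauge}.
#' @return Missing tissue in mm: full gauge extent minus visible extent
#'   (e.g. 1.9 mm visible on the 6 mm gauge gives 4.1 mm).
#' @export
missing_tissue_from_visible <- function(visible_extent, gauge) {
  ext <- gauge_extent(gauge)
  if (!is_num1(visible_extent) || visible_extent < 0 || visible_extent > ext)
    stopf("visible_extent must lie in [0, %g] mm", ext)
  ext - visible_extent
}

#' Measure one chest-wall gauge
#'
#' Steps are examined on the slice of maximal gauge contrast (plus/minus one
#' slice, averaged). A step is visible when the mean signal over its
#' (pose-corrected) footprint exceeds the local background by
#' \code{k_threshold} background standard deviations; steps whose footprint
#' falls outside the imaged field are not visible. Visible steps are counted
#' contiguously from the deepest step toward the wall, so the visible extent
#' is quantized to whole steps (matching the step-counting protocol); a
#' sub-step interpolated extent is reported alongside as informational.
#'
#' @param volume a \code{recon_volume}.
#' @param gauge a \code{step_gauge}.
#' @param pose a \code{pose_estimate} or \code{NULL}.
#' @param k_threshold visibility threshold in background SDs (default 2).
#' @return An object of class \code{gauge_reading}: gauge id, visible_steps,
#'   visible_extent (mm), missing_tissue (mm), sub-step interpolated extent,
#'   per-step means, and a \code{clipped} flag when the gauge region is cut
#'   by the lateral volume boundary.
#' @export
measure_gauge <- function(volume, gauge, pose = NULL, k_threshold = 2) {
  stopifnot(inherits(gauge, "step_gauge"))
  n <- gauge$n_steps
  inc <- gauge$step_increment
  xs <- vol_x(volume); ys <- vol_y(volume)

  # pose-corrected step centers
  steps <- data.frame(x = rep(gauge$lateral_position, n),
                      y = (seq_len(n) - 0.5) * inc,
                      z = rep(gauge$z_center, n))
  pc <- pose_apply(steps, pose)

  # lateral clipping check (x direction); y clipping IS the measurement
  half_w <- gauge$width / 2
  clipped <- any(pc[, "x"] - half_w < min(xs) - 1e-9 |
                 pc[, "x"] + half_w > max(xs) + 1e-9)

  # slice of maximal gauge contrast +/- 1
  gz <- pose_point(gauge$lateral_position, gauge_extent(gauge) / 2,
                   gauge$z_center, pose)[3]
  s0 <- world_to_slice(volume, gz, clamp = TRUE)
  cand <- unique(pmin(pmax(c(s0 - 1, s0, s0 + 1), 1), dim(volume$data)[1]))
  deep <- pc[n, ]  # deepest step footprint as the contrast probe
  probe <- function(s) {
    ci <- which(abs(xs - deep["x"]) <= half_w * 0.8)
    ri <- which(abs(ys - deep["y"]) <= inc * 0.4)
    if (!length(ci) || !length(ri)) return(-Inf)
    mean(volume$data[s, ri, ci])
  }
  s_best <- cand[which.max(vapply(cand, probe, numeric(1)))]
  use_slices <- unique(pmin(pmax(c(s_best - 1, s_best, s_best + 1), 1),
                            dim(volume$data)[1]))

  # local background: strip beside the gauge (offset laterally), same depths
  bg_dx <- gauge$width  # one gauge-width to the side
  step_mean <- rep(NA_real_, n)
  bg_vals <- c()
  for (k in seq_len(n)) {
    ci <- which(abs(xs - pc[k, "x"]) <= half_w * 0.8)
    ri <- which(abs(ys - pc[k, "y"]) <= inc * 0.4)
    if (length(ci) && length(ri)) {
      step_mean[k] <- mean(volume$data[use_slices, ri, ci])
      bci <- which(abs(xs - (pc[k, "x"] + bg_dx)) <= half_w * 0.8)
      if (length(bci))
        bg_vals <- c(bg_vals, as.vector(volume$data[use_slices, ri, bci]))
    }
  }
  if (!length(bg_vals)) {
    # entire gauge outside the imaged depth: nothing visible
    out <- list(gauge_id = gauge$id, visible_steps = 0L,
                visible_extent = 0, missing_tissue = gauge_extent(gauge),
                interp_extent = 0, step_means = step_mean,
                threshold = NA_real_,
                background = c(mean = NA_real_, sd = NA_real_),
                slice = s_best, clipped = clipped)
    class(out) <- "gauge_reading"
    return(out)
  }
  bg_mean <- mean(bg_vals)
  bg_sd <- stats::sd(bg_vals)
  if (!is.finite(bg_sd) || bg_sd == 0) bg_sd <- 0

  thr <- bg_mean + k_threshold * bg_sd
  visible <- !is.na(step_mean) & step_mean > thr

  # contiguous count from the deepest step toward the wall
  vis_steps <- 0L
  for (k in rev(seq_len(n))) {
    if (visible[k]) vis_steps <- vis_steps + 1L else break
  }
  visible_extent <- vis_steps * inc

  # informational sub-step estimate: linear interpolation of the step-mean
  # crossing at the visibility threshold near the last visible step
  interp_extent <- visible_extent
  kedge <- n - vis_steps  # last invisible step index (0 if all visible)
  if (vis_steps > 0 && kedge >= 1 && !is.na(step_mean[kedge]) &&
      is.finite(step_mean[kedge + 1]) && step_mean[kedge + 1] > step_mean[kedge]) {
    frac <- (step_mean[kedge + 1] - thr) /
      (step_mean[kedge + 1] - step_mean[kedge])
    interp_extent <- visible_extent + inc * max(0, min(1, frac))
  }

  out <- list(gauge_id = gauge$id, visible_steps = vis_steps,
              visible_extent = visible_extent,
              missing_tissue = gauge_extent(gauge) - visible_extent,
              interp_extent = min(interp_extent, gauge_extent(gauge)),
              step_means = step_mean, threshold = thr,
              background = c(mean = bg_mean, sd = bg_sd),
              slice = s_best, clipped = clipped)
  class(out) <- "gauge_reading"
  out
}

#' @export
print.gauge_reading <- function(x, ...) {
  cat(sprintf("gauge %s: %d steps visible (%.2g mm), missing tissue %.2g mm%s\n",
              x$gauge_id, x$visible_steps, x$visible_extent,
              x$missing_tissue,
              if (x$clipped) " [gauge clipped by volume boundary]" else ""))
  invisible(x)
}

#' Measure all chest-wall gauges
#'
#' @inheritParams measure_gauge
#' @param geometry a \code{phantom_geometry}.
#' @return List of \code{gauge_reading}s plus the four-gauge mean missing
#'   tissue as attribute \code{"mean_missing_tissue"}.
#' @export
measure_chest_wall <- function(volume, geometry, pose = NULL,
                               k_threshold = 2) {
  readings <- lapply(geometry$gauges, function(g)
    measure_gauge(volume, g, pose = pose, k_threshold = k_threshold))
  attr(readings, "mean_missing_tissue") <-
    mean(vapply(readings, function(r) r$missing_tissue, numeric(1)))
  readings
}
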