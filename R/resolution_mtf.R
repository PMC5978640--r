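# In-plane resolution: PSF patches from ramp beads used as point sources,
# and MTF(x)/MTF(y) from the Fourier transform of the PSF, with optional
# deconvolution of the bead's finite size. The term "MTF" is used in the
# FT-of-PSF sense throughout; for a limited-angle, possibly nonlinear
# reconstruction it is a characterization, not a strict transfer function.

#' Extract a PSF patch around a bead
#'
#' Takes a square patch centered on the (pose-corrected) bead position on
#' its in-focus slice, subtracts the patch-border median as background, and
#' recenters on the intensity centroid. Errors if a secondary peak exceeds
#' 20 percent of the main peak (neighboring-bead contamination).
#'
#' @param volume a \code{recon_volume}.
#' @param bead_xyz numeric xyz (mm) of the bead in phantom coordinates.
#' @param pose a \code{pose_estimate} or \code{NULL}.
#' @param patch_mm patch side length in mm (default 6.4).
#' @param contamination_frac secondary-peak threshold (default 0.2).
#' @return An object of class \code{psf_patch}: \code{data} (2D matrix,
#'   background-subtracted), \code{spacing} (mm), \code{slice},
#'   \code{centroid_offset_px}.
#' @export
extract_psf <- function(volume, bead_xyz, pose = NULL, patch_mm = 6.4,
                        contamination_frac = 0.2) {
  pc <- pose_point(bead_xyz[1], bead_xyz[2], bead_xyz[3], pose)
  dx <- volume$spacing[["dx"]]
  half_px <- max(3L, round(patch_mm / 2 / dx))
  s <- world_to_slice(volume, pc[3])
  if (is.na(s)) stopf("bead slice outside the volume")
  sl <- vol_slice(volume, s)

  grab <- function(r0, c0) {
    ri <- (r0 - half_px):(r0 + half_px)
    ci <- (c0 - half_px):(c0 + half_px)
    if (min(ri) < 1 || min(ci) < 1 || max(ri) > nrow(sl) ||
        max(ci) > ncol(sl))
      stopf("PSF patch extends outside the field")
    sl[ri, ci]
  }
  r0 <- world_to_row(volume, pc[2], clamp = TRUE)
  c0 <- world_to_col(volume, pc[1], clamp = TRUE)
  p <- grab(r0, c0)
  border <- c(p[1, ], p[nrow(p), ], p[, 1], p[, ncol(p)])
  p <- p - stats::median(border)

  # sub-pixel recentering: shift the patch window to the intensity centroid
  w <- pmax(p, 0)
  if (sum(w) <= 0) stopf("PSF patch has no positive signal")
  rr <- row(p); cc <- col(p)
  cen_r <- sum(w * rr) / sum(w); cen_c <- sum(w * cc) / sum(w)
  shift_r <- round(cen_r) - (half_px + 1L)
  shift_c <- round(cen_c) - (half_px + 1L)
  if (shift_r != 0 || shift_c != 0) {
    p <- grab(r0 + shift_r, c0 + shift_c)
    border <- c(p[1, ], p[nrow(p), ], p[, 1], p[, ncol(p)])
    p <- p - stats::median(border)
    w <- pmax(p, 0)
    cen_r <- sum(w * row(p)) / sum(w); cen_c <- sum(w * col(p)) / sum(w)
  }

  # contamination check, scale-free: bin the patch radially from the
  # center; once the per-bin maximum has fallen below the threshold, it
  # must not rise back above it (a rebound is a neighboring bead)
  ctr <- half_px + 1L
  rad <- sqrt((abs(row(p) - ctr) * volume$spacing[["dy"]])^2 +
              (abs(col(p) - ctr) * dx)^2)
  bins <- floor(rad / dx)
  lv <- sort(unique(as.vector(bins)))
  bin_max <- tapply(as.vector(p), factor(as.vector(bins), levels = lv), max)
  thr <- contamination_frac * max(p)
  below <- which(bin_max < thr)
  if (length(below)) {
    after <- bin_max[seq(min(below), length(bin_max))]
    if (max(after) > thr)
      stopf("neighboring-bead contamination: secondary peak %.0f%% of main",
            100 * max(after) / max(p))
  }

  out <- list(data = p, spacing = c(dy = volume$spacing[["dy"]], dx = dx),
              slice = s,
              centroid_offset_px = c(row = cen_r - ctr, col = cen_c - ctr))
  class(out) <- "psf_patch"
  out
}

# |FT| of a uniform disc of diameter d (projected bead), evaluated at
# frequency f (cycles/mm): 2 J1(pi d f) / (pi d f), 1 at f = 0
disc_mtf <- function(f, d) {
  x <- pi * d * f
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- 2 * besselJ(x[nz], 1) / x[nz]
  out
}

#' MTF along x and y from a PSF patch
#'
#' The patch is multiplied by a Hann window (suppressing truncation
#' ripple), zero-padded to four times its size, and transformed with a 2D
#' FFT; the modulation is read along the frequency axes through DC and
#' normalized to 1 at DC. With \code{deconvolve_bead}, the curve is divided
#' by the modulus of the analytic transform of a disc of the bead's
#' projected diameter, with a regularization floor on the divisor: beyond
#' the first frequency where the divisor falls below \code{eps} the curve
#' is truncated and flagged.
#'
#' Modulation values above 1 are reported as-is (anisotropic limited-angle
#' reconstructions can push the apparent MTF above its DC value); nothing
#' is clipped.
#'
#' @param patch a \code{psf_patch}.
#' @param deconvolve_bead divide out the bead's finite size (default
#'   FALSE).
#' @param bead_diameter_mm bead diameter for the deconvolution.
#' @param eps regularization floor for the deconvolution divisor.
#' @param window apply the Hann window (default TRUE).
#' @return List with elements \code{x} and \code{y}, each an
#'   \code{mtf_curve}: \code{frequency} (cycles/mm, 0 to Nyquist),
#'   \code{modulation}, \code{axis}, \code{deconvolved}, \code{truncated}.
#' @export
mtf_from_psf <- function(patch, deconvolve_bead = FALSE,
                         bead_diameter_mm = 0.18, eps = 0.05,
                         window = TRUE) {
  stopifnot(inherits(patch, "psf_patch"))
  p <- patch$data
  n <- nrow(p)
  if (sum(p) <= 0) stopf("patch sum must be > 0")
  if (window) {
    h <- 0.5 * (1 + cos(2 * pi * (seq_len(n) - (n + 1) / 2) / n))
    p <- p * outer(h, h)
  }
  pad <- 4L * n
  big <- matrix(0, pad, pad)
  big[seq_len(n), seq_len(n)] <- p
  FT <- stats::fft(big)
  mod <- Mod(FT)
  if (mod[1, 1] <= 0) stopf("zero DC component")
  mod <- mod / mod[1, 1]

  nyq_x <- 1 / (2 * patch$spacing[["dx"]])
  nyq_y <- 1 / (2 * patch$spacing[["dy"]])
  half <- seq_len(pad %/% 2 + 1L)
  freq_x <- (half - 1) / (pad * patch$spacing[["dx"]])
  freq_y <- (half - 1) / (pad * patch$spacing[["dy"]])

  mk <- function(freq, modv, axis, nyq) {
    keep <- freq <= nyq + 1e-9
    freq <- freq[keep]; modv <- modv[keep]
    truncated <- FALSE
    if (deconvolve_bead) {
      div <- abs(disc_mtf(freq, bead_diameter_mm))
      bad <- which(div < eps)
      if (length(bad)) {
        cut <- min(bad) - 1L
        freq <- freq[seq_len(cut)]; modv <- modv[seq_len(cut)]
        div <- div[seq_len(cut)]
        truncated <- TRUE
      }
      modv <- modv / div
    }
    out <- list(frequency = freq, modulation = modv, axis = axis,
                deconvolved = isTRUE(deconvolve_bead),
                truncated = truncated)
    class(out) <- "mtf_curve"
    out
  }
  # rows index y, columns index x
  list(x = mk(freq_x, mod[1, half], "x", nyq_x),
       y = mk(freq_y, mod[half, 1], "y", nyq_y))
}

#' Average replicate MTF curves
#'
#' Pointwise mean of curves sharing an axis and frequency grid, with
#' per-frequency SD reported.
#'
#' @param curves list of \code{mtf_curve}s.
#' @return An \code{mtf_curve} with an extra \code{sd} element.
#' @export
average_mtf <- function(curves) {
  stopifnot(length(curves) >= 1)
  axes <- vapply(curves, function(cv) cv$axis, character(1))
  if (length(unique(axes)) != 1) stopf("cannot average mixed-axis MTF curves")
  nf <- min(vapply(curves, function(cv) length(cv$frequency), integer(1)))
  f0 <- curves[[1]]$frequency[seq_len(nf)]
  for (cv in curves)
    if (max(abs(cv$frequency[seq_len(nf)] - f0)) > 1e-9)
      stopf("curves do not share a frequency grid")
  m <- vapply(curves, function(cv) cv$modulation[seq_len(nf)], numeric(nf))
  m <- matrix(m, nrow = nf)
  out <- list(frequency = f0, modulation = rowMeans(m),
              sd = apply(m, 1, stats::sd), axis = axes[1],
              deconvolved = curves[[1]]$deconvolved,
              truncated = any(vapply(curves, function(cv) cv$truncated,
                                     logical(1))),
              n = length(curves))
  class(out) <- "mtf_curve"
  out
}

#' @export
print.mtf_curve <- function(x, ...) {
  f50 <- tryCatch({
    i <- which(x$modulation < 0.5)[1]
    if (is.na(i) || i < 2) NA_real_ else
      stats::approx(x$modulation[(i - 1):i], x$frequency[(i - 1):i],
                    xout = 0.5)$y
  }, error = function(e) NA_real_)
  cat(sprintf("MTF(%s)%s: %d frequencies to %.2f cycles/mm, f50 = %.2f%s\n",
              x$axis, if (x$deconvolved) " [bead-deconvolved]" else "",
              length(x$frequency), max(x$frequency), f50,
              if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}

#' @export
plot.mtf_curve <- function(x, ...) {
  graphics::plot(x$frequency, x$modulation, type = "l",
                 xlab = "frequency (cycles/mm)", ylab = "modulation",
                 main = sprintf("MTF(%s)", x$axis), ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Export an MTF curve as CSV
#' @param curve an \code{mtf_curve}.
#' @param path output CSV path.
#' @export
write_mtf_csv <- function(curve, path) {
  utils::write.csv(data.frame(frequency_cycles_mm = curve$frequency,
                              modulation = curve$modulation),
                   path, row.names = FALSE)
  invisible(path)
}

#' Headline MTF from the ramp beads of a volume
#'
#' Uses only beads within \code{focus_mm} of the in-focus plane of the
#' chosen slice (beads further from the slice center blur more), extracts
#' a PSF per bead, and averages the per-bead MTF curves per axis. Beads
#' whose patches are contaminated by neighbors are skipped.
#'
#' @param volume a \code{recon_volume}.
#' @param geometry a \code{phantom_geometry}.
#' @param pose a \code{pose_estimate} or \code{NULL}.
#' @param focus_mm keep beads within this |z - slice z| (default 0.5).
#' @param patch_mm per-bead patch size; the default (0.9) stays inside the
#'   default 1 mm in-plane bead pitch.
#' @param deconvolve_bead divide out the bead size (default FALSE).
#' @return List with averaged \code{x} and \code{y} \code{mtf_curve}s and
#'   \code{n_beads} used.
#' @export
volume_mtf <- function(volume, geometry, pose = NULL, focus_mm = 0.5,
                       patch_mm = 0.9, deconvolve_bead = FALSE) {
  zs <- vol_z(volume)
  cx <- list(); cy <- list()
  for (r in geometry$ramps) {
    bp <- bead_positions(r)
    for (i in seq_len(nrow(bp))) {
      pz <- pose_point(bp$x[i], bp$y[i], bp$z[i], pose)[3]
      s <- world_to_slice(volume, pz)
      if (is.na(s) || abs(zs[s] - pz) > focus_mm) next
      res <- tryCatch({
        patch <- extract_psf(volume, c(bp$x[i], bp$y[i], bp$z[i]),
                             pose = pose, patch_mm = patch_mm)
        mtf_from_psf(patch, deconvolve_bead = deconvolve_bead,
                     bead_diameter_mm = r$bead_diameter)
      }, error = function(e) NULL)
      if (!is.null(res)) {
        cx[[length(cx) + 1L]] <- res$x
        cy[[length(cy) + 1L]] <- res$y
      }
    }
  }
  if (!length(cx)) stopf("no usable in-focus beads for MTF")
  list(x = average_mtf(cx), y = average_mtf(cy), n_beads = length(cx))
}
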