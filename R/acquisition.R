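# Acquisition model: everything the simulator needs to turn the geometry
# into a degraded reconstructed volume.

#' Acquisition model for the phantom simulator
#'
#' Parameterizes the degradations applied when rendering a synthetic
#' reconstructed DBT volume: the through-plane slice profile (whose FWHM is
#' the nominal slice width), anisotropic in-plane Gaussian blur, additive
#' Gaussian noise whose standard deviation scales as a power of mAs
#' (exponent -0.5 by default, the usual square-root exposure dependence),
#' and a rigid pose perturbation of the phantom.
#'
#' @param pixel_spacing_xy in-plane pixel spacing in mm (default 0.1).
#' @param slice_increment spacing between reconstructed slices in mm
#'   (default 1).
#' @param nominal_slice_width FWHM of the slice profile in mm (default 1).
#' @param slice_profile one of \code{"gaussian"}, \code{"triangular"},
#'   \code{"rectangular"}; the profile's FWHM equals
#'   \code{nominal_slice_width}.
#' @param blur_sigma_x,blur_sigma_y in-plane Gaussian blur sigmas in mm.
#'   The default is wider along x (tube-travel direction), giving the
#'   expected MTF anisotropy.
#' @param noise_base_sd noise SD (in background units) at \code{ref_mas}.
#' @param noise_exponent exponent b in SD = base_sd * (mAs/ref_mas)^b.
#' @param mas exposure (mAs) of the rendered volume.
#' @param ref_mas reference mAs at which \code{noise_base_sd} applies.
#' @param pose_deg rotations c(roll, pitch, yaw) in degrees applied to the
#'   phantom about its center before sampling.
#' @param translation_mm rigid in-plane translation c(x, y) in mm.
#' @param background_level intensity of the phantom background material.
#' @param seed integer seed for the noise realization.
#' @return An object of class \code{acquisition_model}.
#' @export
acquisition_model <- function(pixel_spacing_xy = 0.1, slice_increment = 1,
                              nominal_slice_width = 1,
                              slice_profile = c("gaussian", "triangular",
                                                "rectangular"),
                              blur_sigma_x = 0.15, blur_sigma_y = 0.10,
                              noise_base_sd = 1.0, noise_exponent = -0.5,
                              mas = 100, ref_mas = 100,
                              pose_deg = c(0, 0, 0),
                              translation_mm = c(0, 0),
                              background_level = 100, seed = 1L) {
  slice_profile <- match.arg(slice_profile)
  if (pixel_spacing_xy <= 0 || slice_increment <= 0)
    stopf("spacings must be > 0")
  if (nominal_slice_width <= 0) stopf("nominal_slice_width must be > 0")
  if (noise_base_sd < 0) stopf("noise SD must be >= 0")
  if (mas <= 0 || ref_mas <= 0) stopf("mAs must be > 0")
  stopifnot(length(pose_deg) == 3, length(translation_mm) == 2)
  acq <- list(pixel_spacing_xy = pixel_spacing_xy,
              slice_increment = slice_increment,
              nominal_slice_width = nominal_slice_width,
              slice_profile = slice_profile,
              blur_sigma_x = blur_sigma_x, blur_sigma_y = blur_sigma_y,
              noise_base_sd = noise_base_sd, noise_exponent = noise_exponent,
              mas = mas, ref_mas = ref_mas,
              pose_deg = as.numeric(pose_deg),
              translation_mm = as.numeric(translation_mm),
              background_level = background_level, seed = as.integer(seed))
  class(acq) <- "acquisition_model"
  acq
}

#' Noise standard deviation implied by an acquisition model
#' @param acq an \code{acquisition_model}.
#' @param mas optional mAs overriding the model's own.
#' @export
noise_sd <- function(acq, mas = acq$mas) {
  acq$noise_base_sd * (mas / acq$ref_mas)^acq$noise_exponent
}

#' @export
print.acquisition_model <- function(x, ...) {
  cat("DBT acquisition model\n")
  cat(sprintf("  grid: %.3g mm pixels, %.3g mm slice increment\n",
              x$pixel_spacing_xy, x$slice_increment))
  cat(sprintf("  slice profile: %s, FWHM %.3g mm\n",
              x$slice_profile, x$nominal_slice_width))
  cat(sprintf("  in-plane blur: sigma_x %.3g, sigma_y %.3g mm\n",
              x$blur_sigma_x, x$blur_sigma_y))
  cat(sprintf("  noise: SD %.3g at %g mAs (exponent %.3g), rendered at %g mAs -> SD %.3g\n",
              x$noise_base_sd, x$ref_mas, x$noise_exponent, x$mas,
              noise_sd(x)))
  cat(sprintf("  pose (roll, pitch, yaw): %s deg; translation (%g, %g) mm\n",
              paste(format(x$pose_deg), collapse = ", "),
              x$translation_mm[1], x$translation_mm[2]))
  invisible(x)
}

## ---- slice profile ---------------------------------------------------------

# S(t): through-plane sensitivity, peak 1, FWHM = width.
# profile_cdf: integral of S from -Inf to t (same units, mm).
# profile_norm: integral of S over the real line.
# profile_halfsupport: |t| beyond which S is negligible.

profile_sigma <- function(width) width / (2 * sqrt(2 * log(2)))

profile_fun <- function(shape, width) {
  switch(shape,
    rectangular = function(t) as.numeric(abs(t) <= width / 2),
    triangular = function(t) pmax(0, 1 - abs(t) / width),
    gaussian = {
      s <- profile_sigma(width)
      function(t) exp(-t^2 / (2 * s^2))
    })
}

profile_cdf <- function(shape, width) {
  switch(shape,
    rectangular = function(t) pmin(pmax(t, -width / 2), width / 2) + width / 2,
    triangular = function(t) {
      t <- pmin(pmax(t, -width), width)
      ifelse(t < 0, (t + width)^2 / (2 * width),
             width / 2 + t - t^2 / (2 * width))
    },
    gaussian = {
      s <- profile_sigma(width)
      function(t) s * sqrt(2 * pi) * stats::pnorm(t / s)
    })
}

profile_norm <- function(shape, width) {
  switch(shape, rectangular = width, triangular = width,
         gaussian = profile_sigma(width) * sqrt(2 * pi))
}

profile_halfsupport <- function(shape, width) {
  switch(shape, rectangular = width / 2, triangular = width,
         gaussian = 4.5 * profile_sigma(width))
}
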