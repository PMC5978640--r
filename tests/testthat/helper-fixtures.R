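# Shared fixtures: all volumes are rendered in code at test time and cached
# for the session. Regions are kept small (a strip around the objects a
# test measures) so the suite stays fast.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

fx_geometry <- function() fx_cache("geom", default_geometry)

# strip covering both folded ramps (full x), all slices
ramp_region <- function() list(min = c(x = -48, y = 18, z = 0),
                               max = c(x = 48, y = 32, z = 42))

fx_ramp_volume <- function(width = 1, seed = 1, noise = 1,
                           profile = "gaussian", slice_increment = 1) {
  key <- sprintf("ramp_w%g_s%d_n%g_%s_dz%g", width, seed, noise, profile,
                 slice_increment)
  fx_cache(key, function() {
    acq <- acquisition_model(nominal_slice_width = width, seed = seed,
                             noise_base_sd = noise, slice_profile = profile,
                             slice_increment = slice_increment)
    render(fx_geometry(), acq, region = ramp_region())
  })
}

# strip covering the three 5 mm z-geometry beads
zbead_region <- function() list(min = c(x = -20, y = 6, z = 0),
                                max = c(x = 20, y = 22, z = 42))

fx_zbead_volume <- function(seed = 3, noise = 1) {
  fx_cache(sprintf("zbead_s%d_n%g", seed, noise), function() {
    render(fx_geometry(),
           acquisition_model(seed = seed, noise_base_sd = noise),
           region = zbead_region())
  })
}

# strip around one gauge (gauge 2 at x = -12), cropped at depth `crop`
gauge_region <- function(crop = 0) list(min = c(x = -20, y = crop, z = 0),
                                        max = c(x = -4, y = 12, z = 42))

fx_gauge_volume <- function(crop = 0, noise = 0, seed = 2) {
  fx_cache(sprintf("gauge_c%g_n%g_s%d", crop, noise, seed), function() {
    render(fx_geometry(),
           acquisition_model(noise_base_sd = noise, seed = seed),
           region = gauge_region(crop))
  })
}

# full-phantom render at 0.2 mm pixels (pipeline / uniformity fixture)
fx_full_volume <- function(seed = 7) {
  fx_cache(sprintf("full02_s%d", seed), function() {
    render(fx_geometry(),
           acquisition_model(pixel_spacing_xy = 0.2, seed = seed))
  })
}

# geometry holding a single isolated point-like ramp bead (for PSF/MTF)
single_bead_geometry <- function(d = 0.02, contrast = 50) {
  g <- default_geometry()
  g$ramps <- list(bead_ramp(bead_diameter = d, x_start = 0, x_pitch = 1,
                            y_lower = 40, y_upper = 41, z_base = 21,
                            total_rise = 0, contrast = contrast))
  g$low_contrast_spheres <- g$low_contrast_spheres[0, ]
  g$z_beads <- g$z_beads[0, ]
  g$alignment_markers <- g$alignment_markers[0, ]
  g$gauges <- list()
  g$al_square$contrast <- 0
  g
}

bead_region <- function() list(min = c(x = -6, y = 34, z = 16),
                               max = c(x = 6, y = 46, z = 26))

fx_psf_volume <- function(sx = 0.2, sy = 0.2) {
  fx_cache(sprintf("psf_%g_%g", sx, sy), function() {
    render(single_bead_geometry(),
           acquisition_model(blur_sigma_x = sx, blur_sigma_y = sy,
                             noise_base_sd = 0), region = bead_region())
  })
}

# geometry with only the four alignment markers (pose tests)
markers_geometry <- function() {
  g <- default_geometry()
  g$low_contrast_spheres <- g$low_contrast_spheres[0, ]
  g$z_beads <- g$z_beads[0, ]
  g$gauges <- list()
  g$ramps <- list()
  g$al_square$contrast <- 0
  g
}

fx_marker_volume <- function(pose = c(0, 0, 0), translation = c(0, 0),
                             seed = 5, noise = 1) {
  key <- sprintf("mark_%s_%s_s%d_n%g", paste(pose, collapse = "_"),
                 paste(translation, collapse = "_"), seed, noise)
  fx_cache(key, function() {
    render(markers_geometry(),
           acquisition_model(pixel_spacing_xy = 0.2, pose_deg = pose,
                             translation_mm = translation, seed = seed,
                             noise_base_sd = noise))
  })
}

# a synthetic constant recon_volume (no render needed)
flat_volume <- function(value = 100, nx = 60, ny = 60, nz = 3,
                        spacing = c(1, 0.5, 0.5)) {
  recon_volume(array(value, dim = c(nz, ny, nx)), spacing = spacing)
}
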