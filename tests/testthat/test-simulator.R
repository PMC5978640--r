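empty_geometry <- function() {
  g <- default_geometry()
  g$low_contrast_spheres <- g$low_contrast_spheres[0, ]
  g$z_beads <- g$z_beads[0, ]
  g$alignment_markers <- g$alignment_markers[0, ]
  g$gauges <- list()
  g$ramps <- list()
  g$al_square$contrast <- 0
  g
}

small_region <- function() list(min = c(x = -5, y = 35, z = 16),
                                max = c(x = 5, y = 45, z = 26))

test_that("empty geometry with zero noise renders a constant volume", {
  v <- render(empty_geometry(),
              acquisition_model(noise_base_sd = 0, background_level = 123),
              region = small_region())
  expect_lt(max(abs(v$data - 123)), 1e-9)
  expect_equal(unname(v$spacing), c(1, 0.1, 0.1))
})

test_that("a single bead is brightest on the slice nearest its z", {
  for (prof in c("gaussian", "triangular", "rectangular")) {
    g <- single_bead_geometry(d = 0.18, contrast = 20)
    g$ramps[[1]]$z_base <- 20.6  # off-grid center; nearest slice z = 21
    v <- render(g, acquisition_model(noise_base_sd = 0,
                                     slice_profile = prof),
                region = small_region())
    r0 <- which.min(abs(tomoqa:::vol_y(v) - 40))
    c0 <- which.min(abs(tomoqa:::vol_x(v) - 0))
    prof_z <- v$data[, r0, c0]
    expect_equal(tomoqa:::vol_z(v)[which.max(prof_z)], 21,
                 label = paste("profile", prof))
  }
})

test_that("noise SD follows the mAs power law on rendered volumes", {
  g <- empty_geometry()
  v1 <- render(g, acquisition_model(mas = 100, seed = 4),
               region = small_region())
  v4 <- render(g, acquisition_model(mas = 400, seed = 9),
               region = small_region())
  sd1 <- sd(v1$data); sd4 <- sd(v4$data)
  expect_equal(sd1, 1.0, tolerance = 0.05)   # base SD at reference mAs
  expect_equal(sd1 / sd4, 2, tolerance = 0.1)  # 4x mAs -> half the SD
})

test_that("noise-free net signal is linear in the contrast fraction", {
  mk <- function(cf) {
    g <- default_geometry(sphere_contrast = cf)
    render(g, acquisition_model(noise_base_sd = 0),
           region = list(min = c(x = -10, y = 27, z = 16),
                         max = c(x = 5, y = 41, z = 26)))
  }
  v1 <- mk(0.02); v2 <- mk(0.04)
  g10 <- default_geometry()
  g10$low_contrast_spheres <-
    g10$low_contrast_spheres[g10$low_contrast_spheres$diameter == 10, ]
  net <- function(v) score_spheres(v, g10)$net_signal
  expect_equal(net(v2) / net(v1), 2, tolerance = 1e-6)
})

test_that("zero pose leaves object centroids at their geometric positions", {
  v <- fx_marker_volume(noise = 0)
  cent <- locate_markers(v, default_geometry())
  truth <- as.matrix(default_geometry()$alignment_markers[, c("x", "y", "z")])
  # within one voxel (0.2 mm in-plane, 1 mm through-plane)
  expect_lt(max(abs(cent[, 1:2] - truth[, 1:2])), 0.2)
  expect_lt(max(abs(cent[, 3] - truth[, 3])), 1)
})

test_that("render rejects grids that miss the phantom", {
  g <- default_geometry()
  expect_error(render(g, acquisition_model(),
                      region = list(min = c(x = 200, y = 200, z = 100),
                                    max = c(x = 210, y = 210, z = 110))),
               "bounding box")
  expect_error(render(g, acquisition_model(),
                      region = list(min = c(x = 5, y = 5, z = 5),
                                    max = c(x = 5, y = 50, z = 40))),
               "extent")
})

test_that("render_series is reproducible and scales noise across mAs", {
  g <- empty_geometry()
  acq <- acquisition_model(seed = 11)
  one <- render_series(g, acq, 50, region = small_region())
  expect_length(one, 1L)

  # zero base SD: all volumes identical regardless of mAs
  acq0 <- acquisition_model(noise_base_sd = 0)
  vs <- render_series(g, acq0, c(25, 50, 100), region = small_region())
  expect_length(vs, 3L)
  expect_identical(vs[[1]]$data, vs[[2]]$data)
  expect_identical(vs[[2]]$data, vs[[3]]$data)

  # measured SD ratio across a 4x mAs span
  vs2 <- render_series(g, acq, c(25, 100), region = small_region())
  expect_equal(sd(vs2[[1]]$data) / sd(vs2[[2]]$data), 2, tolerance = 0.1)

  # same seed -> identical realization; different seed -> different
  again <- render_series(g, acq, c(25, 100), region = small_region())
  expect_identical(vs2[[1]]$data, again[[1]]$data)
  acq2 <- acquisition_model(seed = 12)
  other <- render_series(g, acq2, c(25, 100), region = small_region())
  expect_false(identical(vs2[[1]]$data, other[[1]]$data))

  expect_error(render_series(g, acq, numeric(0)), "non-empty")
  expect_error(render_series(g, acq, c(50, -1)), "positive")
})

test_that("every rendered volume carries a usable truth record", {
  v <- fx_zbead_volume()
  tr <- render_truth(v)
  expect_equal(tr$slice_width, 1)
  expect_equal(tr$noise_sd, 1)
  expect_equal(tr$pose_deg, c(0, 0, 0))
  expect_equal(unname(tr$z_beads[, "z"]), c(11, 21, 31))
})
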