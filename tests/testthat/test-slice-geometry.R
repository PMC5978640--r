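test_that("fwhm recovers closed-form widths on synthetic curves", {
  z <- seq(-6, 6, by = 0.01)
  # rectangle of width 3
  rect <- list(z = z, sensitivity = as.numeric(abs(z) <= 1.5))
  expect_equal(fwhm(rect), 3.0, tolerance = 0.011)
  # Gaussian sigma 1 -> 2*sqrt(2 log 2)
  gaus <- list(z = z, sensitivity = exp(-z^2 / 2))
  expect_equal(fwhm(gaus), 2.3548, tolerance = 1e-3)
  # truncated profile: no right crossing
  trunc <- list(z = z, sensitivity = exp(-(z - 5.9)^2 / 2))
  expect_error(fwhm(trunc), "truncated")
})

test_that("SSP reproduces the simulated slice profile without noise", {
  g <- fx_geometry()
  # rectangular profile of width 3: SSP is a rectangle of width 3
  v <- fx_ramp_volume(width = 3, noise = 0, profile = "rectangular")
  cv <- extract_ssp(v, g$ramps[[1]])
  expect_equal(cv$fwhm, 3.0, tolerance = 0.1)
  inner <- abs(cv$z - 21) < 1.2
  outer_ <- abs(cv$z - 21) > 2.0
  expect_gt(min(cv$sensitivity[inner]), 0.9)
  expect_lt(max(cv$sensitivity[outer_]), 0.15)

  # Gaussian profile: peak sits at the slice's true z within a bead spacing
  vg <- fx_ramp_volume(width = 2, noise = 0)
  cg <- extract_ssp(vg, g$ramps[[1]])
  expect_lt(abs(cg$z[which.max(cg$sensitivity)] - 21), 0.25)
  expect_equal(cg$fwhm, 2.0, tolerance = 0.1)
})

test_that("left and right folded ramps agree on the slice width", {
  g <- fx_geometry()
  v <- fx_ramp_volume(width = 2, seed = 5)
  fl <- extract_ssp(v, g$ramps[[1]])$fwhm
  fr <- extract_ssp(v, g$ramps[[2]])$fwhm
  expect_lt(abs(fl - fr) / fl, 0.10)
})

test_that("SSP errors when too few peaks are resolvable", {
  g <- fx_geometry()
  v <- fx_ramp_volume(width = 1, noise = 0)
  # restrict to a region holding almost none of the left ramp's beads
  vsub <- v
  keep <- tomoqa:::vol_x(v) > 44
  vsub$data <- v$data[, , keep, drop = FALSE]
  vsub$origin[["x"]] <- tomoqa:::vol_x(v)[keep][1]
  expect_error(extract_ssp(vsub, g$ramps[[1]]), "fewer than 5")
})

test_that("slice incrementation matches the reconstruction grid", {
  g <- fx_geometry()
  v <- fx_ramp_volume(width = 2, seed = 8)
  si <- slice_incrementation(v, g$ramps[[1]])
  expect_equal(si$increment_mm, 1.0, tolerance = 0.1)
  expect_length(si$outliers, 0L)

  v5 <- fx_ramp_volume(width = 2, seed = 8, slice_increment = 0.5)
  si5 <- slice_incrementation(v5, g$ramps[[1]])
  expect_equal(si5$increment_mm, 0.5, tolerance = 0.1)

  # a duplicated slice shows up as an increment outlier
  vdup <- v
  s0 <- tomoqa:::world_to_slice(v, 21)
  vdup$data[s0 + 1, , ] <- vdup$data[s0, , ]
  sid <- slice_incrementation(vdup, g$ramps[[1]])
  expect_gt(length(sid$outliers), 0L)
})

test_that("z-bead spacing recovers simulated geometry", {
  g <- fx_geometry()
  v <- fx_zbead_volume()
  zg <- z_bead_spacing(v, g)
  expect_equal(zg$spacings_mm, c(10, 10), tolerance = 0.03)

  # beads placed 8 mm apart
  g8 <- g
  g8$z_beads$z <- c(13, 21, 29)
  v8 <- fx_cache("zbead8", function()
    render(g8, acquisition_model(seed = 4), region = zbead_region()))
  zg8 <- z_bead_spacing(v8, g8)
  expect_equal(zg8$spacings_mm, c(8, 8), tolerance = 0.3)

  # two beads at identical z -> spacing 0
  g0 <- g
  g0$z_beads <- data.frame(x = c(-12, 12), y = 14, z = 21, diameter = 5,
                           contrast = 1)
  v0 <- fx_cache("zbead0", function()
    render(g0, acquisition_model(seed = 4), region = zbead_region()))
  expect_equal(z_bead_spacing(v0, g0)$spacings_mm, 0, tolerance = 0.2)

  # a bead outside the field is reported by index
  vcrop <- fx_cache("zbead_crop", function()
    render(g, acquisition_model(seed = 4),
           region = list(min = c(x = -5, y = 6, z = 0),
                         max = c(x = 20, y = 22, z = 42))))
  expect_error(z_bead_spacing(vcrop, g), "bead 1")
})

test_that("z-bead spacing is invariant under in-plane translation", {
  g <- fx_geometry()
  v <- fx_zbead_volume()
  base <- z_bead_spacing(v, g)$spacings_mm
  vsh <- fx_cache("zbead_shift", function()
    render(g, acquisition_model(seed = 3, translation_mm = c(3, -2)),
           region = zbead_region()))
  pose <- identity_pose(g)
  pose$translation <- c(x = 3, y = -2)
  shifted <- z_bead_spacing(vsh, g, pose = pose)$spacings_mm
  expect_equal(shifted, base, tolerance = 0.05)
})

test_that("ASF is symmetric for isotropic blur and wider along the blurred axis", {
  g <- fx_geometry()
  viso <- fx_cache("asf_iso", function()
    render(g, acquisition_model(blur_sigma_x = 0.12, blur_sigma_y = 0.12,
                                noise_base_sd = 0), region = zbead_region()))
  a <- asf(viso, g)
  # in-focus slice: peak at offset 0
  expect_lt(abs(a$x$offset[which.max(a$x$response)]), 0.11)
  expect_lt(abs(a$y$offset[which.max(a$y$response)]), 0.11)
  # isotropic: x and y widths agree
  wx <- fwhm(list(z = a$x$offset, sensitivity = a$x$response))
  wy <- fwhm(list(z = a$y$offset, sensitivity = a$y$response))
  expect_equal(wx, wy, tolerance = 0.05)

  vani <- fx_cache("asf_ani", function()
    render(g, acquisition_model(blur_sigma_x = 0.5, blur_sigma_y = 0.1,
                                noise_base_sd = 0), region = zbead_region()))
  b <- asf(vani, g)
  bx <- fwhm(list(z = b$x$offset, sensitivity = b$x$response))
  by <- fwhm(list(z = b$y$offset, sensitivity = b$y$response))
  expect_gt(bx, by)
})

test_that("the folded ramp set spans its full rise in a noiseless volume", {
  g <- fx_geometry()
  v <- fx_ramp_volume(width = 1, noise = 0)
  ze <- ramp_z_extent(v, g$ramps[[1]])
  expect_identical(ze$n_detected, nrow(bead_positions(g$ramps[[1]])))
  expect_equal(ze$z_extent_mm, 10.0, tolerance = 1e-9)
})

test_that("curve CSV export carries the sampled values", {
  g <- fx_geometry()
  v <- fx_ramp_volume(width = 2, noise = 0)
  cv <- extract_ssp(v, g$ramps[[1]])
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, path)
  back <- utils::read.csv(path)
  expect_named(back, c("z_mm", "sensitivity"))
  expect_equal(nrow(back), length(cv$z))
})
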