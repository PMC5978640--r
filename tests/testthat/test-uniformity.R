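test_that("constant volumes give equal ROI means, zero SD, 0% uniformity", {
  g <- fx_geometry()
  v <- fx_cache("flat_small", function()
    render(g, acquisition_model(pixel_spacing_xy = 0.2, noise_base_sd = 0),
           region = list(min = c(x = -50, y = 0, z = 18),
                         max = c(x = 50, y = 80, z = 24))))
  ru <- regional_uniformity(v, g, slices = 2:4)
  expect_true(all(abs(ru$mean - 100) < 1e-6))
  expect_true(all(ru$sd < 1e-6))
  gu <- global_uniformity(v, g)
  expect_equal(gu$percent, 0, tolerance = 1e-9)
  expect_named(gu$roi_means, paste0("g", 1:5))
})

test_that("a linear z gradient shows up as the regional trend", {
  # constructed volume: background rising 0.5 units per mm of z
  nz <- 9
  arr <- array(rep(100 + 0.5 * (0:(nz - 1)), each = 1), dim = c(nz, 400, 500))
  v <- recon_volume(arr, spacing = c(1, 0.2, 0.2),
                    origin = c(x = -50, y = 0, z = 17))
  g <- fx_geometry()
  ru <- regional_uniformity(v, g)
  tr <- attr(ru, "trend")
  expect_equal(unname(tr["anterior"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(tr["lateral"]), 0.5, tolerance = 1e-6)
})

test_that("measured ROI noise matches the injected noise SD", {
  g <- fx_geometry()
  v <- fx_full_volume()
  ru <- regional_uniformity(v, g, slices = 20:24)
  truth_sd <- render_truth(v)$noise_sd
  expect_lt(max(abs(ru$sd - truth_sd) / truth_sd), 0.15)
})

test_that("ROIs that touch test objects are refused", {
  g <- fx_geometry()
  v <- fx_full_volume()
  bad <- data.frame(id = "over_square", x = g$al_square$center[["x"]],
                    y = g$al_square$center[["y"]], radius = 5)
  expect_error(regional_uniformity(v, g, rois = bad), "overlaps")
  expect_error(global_uniformity(v, g, rois = rbind(bad, bad)), "overlaps")
})

test_that("global uniformity recovers an injected 5% offset", {
  g <- fx_geometry()
  v0 <- fx_full_volume()
  s <- tomoqa:::world_to_slice(v0, g$test_plane_z)
  rois <- default_rois(g)$global_rois
  v <- v0
  # lift the background by 5% inside the first ROI's disc
  xs <- tomoqa:::vol_x(v); ys <- tomoqa:::vol_y(v)
  msk <- outer((ys - rois$y[1])^2, (xs - rois$x[1])^2, "+") <= rois$radius[1]^2
  sl <- v$data[s, , ]
  sl[msk] <- sl[msk] * 1.05
  v$data[s, , ] <- sl
  gu <- global_uniformity(v, g)
  expect_equal(gu$percent, 5, tolerance = 0.5)
})

test_that("global uniformity is scale-invariant but offset-sensitive", {
  g <- fx_geometry()
  v <- fx_full_volume()
  base <- global_uniformity(v, g)$percent
  vs <- v; vs$data <- v$data * 3
  expect_equal(global_uniformity(vs, g)$percent, base, tolerance = 1e-9)
  va <- v; va$data <- v$data + 500
  expect_lt(global_uniformity(va, g)$percent, base)
})

test_that("uniformity is unaffected by the presence of test objects", {
  g <- fx_geometry()
  v_obj <- fx_full_volume()
  g_empty <- g
  g_empty$low_contrast_spheres <- g_empty$low_contrast_spheres[0, ]
  g_empty$z_beads <- g_empty$z_beads[0, ]
  g_empty$gauges <- list(); g_empty$ramps <- list()
  g_empty$al_square$contrast <- 0
  g_empty$alignment_markers <- g_empty$alignment_markers[0, ]
  v_flat <- fx_cache("full02_noobj", function()
    render(g_empty, acquisition_model(pixel_spacing_xy = 0.2, seed = 7)))
  d <- abs(global_uniformity(v_obj, g)$percent -
             global_uniformity(v_flat, g)$percent)
  expect_lt(d, 0.5)
})

test_that("SNR and CNR follow their definitions", {
  g <- fx_geometry()
  v <- fx_full_volume()
  sn <- snr(v, g)
  # net signal / noise SD at zero offset on the raw pixel scale
  expect_equal(sn$snr, sn$signal_mean / sn$noise_sd, tolerance = 1e-12)
  expect_equal(sn$signal_mean, 100, tolerance = 1)
  expect_equal(sn$offset, 0)

  cn <- cnr(v, g)
  expect_equal(cn$cnr, (cn$al_mean - cn$bg_mean) / cn$bg_sd,
               tolerance = 1e-12)
  expect_gt(cn$cnr, 5)

  # degenerate noiseless volume flags infinite SNR
  v0 <- fx_cache("flat_small", function()
    render(g, acquisition_model(pixel_spacing_xy = 0.2, noise_base_sd = 0),
           region = list(min = c(x = -50, y = 0, z = 18),
                         max = c(x = 50, y = 80, z = 24))))
  sn0 <- snr(v0, g)
  expect_true(sn0$degenerate)
  expect_identical(sn0$snr, Inf)
})

test_that("the noise power-law fit recovers closed-form inputs", {
  mas <- c(25, 50, 100, 200)
  exact <- data.frame(mas = mas, sd = 50 * mas^(-0.5))
  f <- fit_noise_vs_mas(exact)
  expect_equal(f$b, -0.5, tolerance = 1e-12)
  expect_equal(f$a, 50, tolerance = 1e-9)
  expect_equal(f$residual, 0, tolerance = 1e-12)
  expect_equal(unname(coef(f)["b"]), f$b)
  expect_equal(predict(f, 400), 2.5, tolerance = 1e-9)

  flat <- data.frame(mas = mas, sd = rep(7, 4))
  expect_equal(fit_noise_vs_mas(flat)$b, 0, tolerance = 1e-12)

  expect_error(fit_noise_vs_mas(data.frame(mas = c(10, 20), sd = c(1, 2))),
               ">= 3")
  expect_error(fit_noise_vs_mas(data.frame(mas = mas, sd = c(-1, 1, 1, 1))),
               "positive")
})
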