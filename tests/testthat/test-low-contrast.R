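test_that("noiseless spheres are all detected with contrast-proportional signal", {
  g <- fx_geometry()
  v <- fx_cache("sphere_plane", function()
    render(g, acquisition_model(noise_base_sd = 0),
           region = list(min = c(x = -25, y = 27, z = 16),
                         max = c(x = 25, y = 68, z = 26))))
  sc <- score_spheres(v, g)
  expect_equal(nrow(sc), 9L)
  expect_true(all(sc$detected))
  expect_true(all(sc$net_signal > 0))
  # net signal grows with diameter (partial-volume dilution shrinks the
  # apparent contrast of sub-slice spheres)
  expect_true(all(diff(sc$net_signal) >= 0))
})

test_that("zero-contrast spheres are never detected", {
  g0 <- default_geometry(sphere_contrast = 0)
  v <- fx_cache("sphere_zeroc", function()
    render(g0, acquisition_model(seed = 17),
           region = list(min = c(x = -25, y = 27, z = 16),
                         max = c(x = 25, y = 68, z = 26))))
  sc <- score_spheres(v, g0)
  expect_false(any(sc$detected))
})

test_that("detection degrades from the smallest diameters as noise grows", {
  g <- fx_geometry()
  region <- list(min = c(x = -25, y = 27, z = 16),
                 max = c(x = 25, y = 68, z = 26))
  smallest_detected <- vapply(c(400, 100, 25), function(mas) {
    v <- fx_cache(sprintf("sphere_mas%d", mas), function()
      render(g, acquisition_model(mas = mas, seed = 19), region = region))
    sc <- score_spheres(v, g)
    if (any(sc$detected)) min(sc$diameter[sc$detected]) else Inf
  }, numeric(1))
  # higher mAs (less noise) never detects fewer/larger spheres
  expect_true(all(diff(smallest_detected) >= 0))
})

test_that("circle-mean SDs follow the white-noise sampling law", {
  # constant region: zero SD
  flat <- matrix(5, 200, 200)
  r0 <- sample_circle_means(flat, 4, 0.1, n_samples = 20)
  expect_equal(r0$sd_of_means, 0, tolerance = 1e-12)

  # white noise sigma: SD of a circle mean is sigma / sqrt(m pixels)
  set.seed(7)
  sigma <- 3
  big <- matrix(rnorm(1500 * 1500, 0, sigma), 1500, 1500)  # 150 x 150 mm
  r4 <- sample_circle_means(big, 4, 0.1, n_samples = 60)
  m4 <- sum(outer(seq(-2, 2, 0.1)[-1]^2, seq(-2, 2, 0.1)[-1]^2,
                  "+") <= 4) # approx pixel count, just for the oracle
  expect_equal(r4$sd_of_means, sigma / sqrt(m4), tolerance = 0.15 * sigma / sqrt(m4))

  # doubling the diameter halves the SD of the means
  r8 <- sample_circle_means(big, 8, 0.1, n_samples = 60)
  expect_equal(r4$sd_of_means / r8$sd_of_means, 2, tolerance = 0.4)

  # insufficient room for non-overlapping circles
  expect_error(sample_circle_means(matrix(0, 50, 50), 4, 0.1),
               "non-overlapping")
})

test_that("hex packing is deterministic and non-overlapping", {
  reg <- list(xmin = 0, xmax = 60, ymin = 0, ymax = 40)
  c1 <- tomoqa:::hex_pack_centers(reg, 6)
  c2 <- tomoqa:::hex_pack_centers(reg, 6)
  expect_identical(c1, c2)
  d <- as.matrix(dist(c1))
  diag(d) <- Inf
  expect_gte(min(d), 6)
  # all circles fully inside the region
  expect_true(all(c1$x >= 3 & c1$x <= 57 & c1$y >= 3 & c1$y <= 37))
})

test_that("the hyperbolic contrast-detail fit recovers k and flags misfit", {
  d <- c(1.5, 2, 3, 4, 6, 8, 10)
  exact <- data.frame(diameter = d, sd_of_means = 5 / d)
  f <- fit_cd_model(exact)
  expect_equal(f$k, 5, tolerance = 1e-12)
  expect_equal(f$residual_rms, 0, tolerance = 1e-12)
  expect_equal(unname(coef(f)["k"]), 5, tolerance = 1e-12)

  flat <- data.frame(diameter = d, sd_of_means = rep(2, 7))
  ff <- fit_cd_model(flat)
  expect_gt(ff$residual_relative, 0.25)  # poor fit flagged by residual

  expect_error(fit_cd_model(exact[1:3, ]), ">= 4")
  expect_error(fit_cd_model(data.frame(diameter = c(-1, 2, 3, 4),
                                       sd_of_means = 1:4)), "positive")
})

test_that("volume-level contrast-detail data fit the hyperbola", {
  g <- fx_geometry()
  v <- fx_full_volume()
  cd <- cd_noise_data(v, g)
  expect_equal(cd$diameter, c(10, 8, 6, 4, 3, 2, 1.5, 1))
  expect_true(all(cd$n_circles >= 6))
  # smaller circles scatter more
  expect_gt(cd$sd_of_means[8], cd$sd_of_means[1])
  f <- fit_cd_model(cd)
  expect_gt(f$k, 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cd_csv(f, path)
  expect_named(utils::read.csv(path),
               c("diameter", "sd_of_means", "n_circles", "model_sd"))
})
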