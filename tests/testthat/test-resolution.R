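delta_patch <- function(n = 33, spacing = 0.1) {
  p <- matrix(0, n, n)
  p[(n + 1) / 2, (n + 1) / 2] <- 1
  structure(list(data = p, spacing = c(dy = spacing, dx = spacing),
                 slice = 1L, centroid_offset_px = c(row = 0, col = 0)),
            class = "psf_patch")
}

test_that("a delta PSF has unit MTF at every frequency", {
  m <- mtf_from_psf(delta_patch())
  expect_equal(m$x$modulation, rep(1, length(m$x$frequency)),
               tolerance = 1e-10)
  expect_equal(m$y$modulation, rep(1, length(m$y$frequency)),
               tolerance = 1e-10)
  expect_equal(max(m$x$frequency), 5)  # Nyquist of 0.1 mm pixels
})

test_that("Gaussian blur yields the closed-form MTF", {
  v <- fx_psf_volume(0.2, 0.2)
  p <- extract_psf(v, c(0, 40, 21))
  # patch second moment matches the blur sigma
  w <- pmax(p$data, 0)
  cc <- col(p$data)
  mu <- sum(w * cc) / sum(w)
  sig <- sqrt(sum(w * (cc - mu)^2) / sum(w)) * p$spacing[["dx"]]
  expect_equal(sig, 0.2, tolerance = 0.05)

  m <- mtf_from_psf(p)
  for (ax in c("x", "y")) {
    keep <- m[[ax]]$frequency <= 2.5  # half-Nyquist
    expected <- exp(-2 * pi^2 * 0.2^2 * m[[ax]]$frequency[keep]^2)
    expect_lt(max(abs(m[[ax]]$modulation[keep] - expected)), 0.03)
  }
})

test_that("anisotropic blur orders MTF(x) below MTF(y)", {
  v <- fx_cache("psf_aniso", function()
    render(single_bead_geometry(),
           acquisition_model(blur_sigma_x = 0.25, blur_sigma_y = 0.12,
                             noise_base_sd = 0), region = bead_region()))
  m <- mtf_from_psf(extract_psf(v, c(0, 40, 21)))
  keep <- m$x$frequency > 0.2 & m$x$frequency <= 4
  expect_true(all(m$x$modulation[keep] < m$y$modulation[keep]))
})

test_that("neighboring beads trigger the contamination error", {
  g <- single_bead_geometry(d = 0.08, contrast = 50)
  # a second bead 0.3 mm away in-plane, sharp enough to be resolved
  g$ramps[[1]] <- bead_ramp(bead_diameter = 0.08, x_start = 0,
                            x_pitch = 0.3, y_lower = 40, y_upper = 40,
                            z_base = 21, total_rise = 0.25,
                            vertical_spacing = 0.25, contrast = 50)
  v <- render(g, acquisition_model(noise_base_sd = 0,
                                   blur_sigma_x = 0.03,
                                   blur_sigma_y = 0.03),
              region = bead_region())
  expect_error(extract_psf(v, c(0, 40, 21), patch_mm = 2),
               "contamination")
})

test_that("deconvolving a point bead's true size changes nothing", {
  v <- fx_psf_volume(0.2, 0.2)
  p <- extract_psf(v, c(0, 40, 21))
  plain <- mtf_from_psf(p)
  dec <- mtf_from_psf(p, deconvolve_bead = TRUE, bead_diameter_mm = 0.02)
  keep <- plain$x$frequency <= 2.5
  expect_lt(max(abs(dec$x$modulation[keep] - plain$x$modulation[keep])),
            0.01)
  expect_true(dec$x$deconvolved)
  expect_false(dec$x$truncated)

  # a real 0.18 mm bead's deconvolution lifts the curve (divisor < 1)
  dec18 <- mtf_from_psf(p, deconvolve_bead = TRUE, bead_diameter_mm = 0.18)
  hi <- plain$x$frequency > 1 & keep
  expect_true(all(dec18$x$modulation[hi] > plain$x$modulation[hi]))
})

test_that("the deconvolution divisor floor truncates and flags the curve", {
  p <- delta_patch()
  # huge bead: disc transform hits its first zero well inside Nyquist
  dec <- mtf_from_psf(p, deconvolve_bead = TRUE, bead_diameter_mm = 2)
  expect_true(dec$x$truncated)
  expect_lt(max(dec$x$frequency), 5)
})

test_that("modulation above unity is reported, never clipped", {
  n <- 33
  p <- matrix(0, n, n)
  p[17, 17] <- 1
  p[17, c(15, 19)] <- -0.25  # negative side lobes boost high frequencies
  patch <- structure(list(data = p, spacing = c(dy = 0.1, dx = 0.1),
                          slice = 1L,
                          centroid_offset_px = c(row = 0, col = 0)),
                     class = "psf_patch")
  m <- mtf_from_psf(patch, window = FALSE)
  expect_gt(max(m$x$modulation), 1)
})

test_that("Parseval's identity holds for the extracted patch", {
  v <- fx_psf_volume(0.2, 0.2)
  p <- extract_psf(v, c(0, 40, 21))$data
  expect_equal(sum(Mod(stats::fft(p))^2) / length(p), sum(p^2),
               tolerance = 1e-10)
})

test_that("replicate averaging reduces MTF noise about like 1/sqrt(n)", {
  set.seed(99)
  mk_noisy <- function() {
    p <- delta_patch()
    p$data <- p$data + matrix(rnorm(33 * 33, 0, 0.005), 33, 33)
    mtf_from_psf(p)$x
  }
  singles <- replicate(10, mk_noisy(), simplify = FALSE)
  avg <- average_mtf(singles)
  expect_equal(avg$n, 10L)
  # identical curves average to themselves with zero SD
  same <- average_mtf(list(singles[[1]], singles[[1]]))
  expect_equal(same$modulation, singles[[1]]$modulation)
  expect_equal(max(same$sd), 0)
  # two curves: pointwise midpoint
  two <- average_mtf(singles[1:2])
  expect_equal(two$modulation,
               (singles[[1]]$modulation + singles[[2]]$modulation) / 2)
  # scatter of replicate means shrinks roughly as 1/sqrt(10): compare the
  # SD across single curves to the across-batch SD of 10-curve means
  f_idx <- which.min(abs(avg$frequency - 2.5))
  vals <- vapply(singles, function(cv) cv$modulation[f_idx], numeric(1))
  batches <- replicate(12, {
    reps <- replicate(10, mk_noisy(), simplify = FALSE)
    average_mtf(reps)$modulation[f_idx]
  })
  ratio <- sd(vals) / sd(batches)
  expect_gt(ratio, sqrt(10) / 2)
  expect_lt(ratio, sqrt(10) * 2)
  # mixed axes refuse to average
  my <- mtf_from_psf(delta_patch())$y
  expect_error(average_mtf(list(singles[[1]], my)), "mixed")
})

test_that("volume-level MTF uses only in-focus beads and averages them", {
  g <- fx_geometry()
  v <- fx_ramp_volume(width = 1, noise = 0)
  m <- volume_mtf(v, g)
  expect_gt(m$n_beads, 2)
  expect_equal(m$x$modulation[1], 1)
  expect_equal(m$y$modulation[1], 1)
  # tube-travel anisotropy of the default blur: MTF(x) below MTF(y)
  keep <- m$x$frequency > 0.5 & m$x$frequency < 3
  expect_true(mean(m$x$modulation[keep] < m$y$modulation[keep]) > 0.9)
})
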