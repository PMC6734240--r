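test_that("a delta PSF returns the input unchanged", {
  sc <- ball_scene(r = 3, conc = 2, background = 0.05)
  st <- render_stack(sc, delta_psf(12), noise = NULL, sampling = test_sampling)
  dec <- deconvolve_mle(st, delta_psf(12),
                        deconv_settings(background_estimate = 0.05))
  expect_lt(max(abs(dec$data - pmax(st$data - 0.05, 0))) / max(st$data), 1e-6)
})

test_that("a blurred point source is restored to its position and sharpened at least 2x", {
  dims <- c(41, 41, 31)
  x0 <- array(0, dims)
  x0[21, 21, 16] <- 100
  kern <- gauss_psf(31 * 0.4)$per_brick_kernels[[1]]
  y <- nucquant:::conv_sep(x0, kern)
  r <- rl_deconvolve(y, kern, deconv_settings(max_iterations = 500,
                                              quality_change_threshold = 1e-5))
  expect_equal(which(r$x == max(r$x)), which(x0 == max(x0)))
  fwhm_z <- function(a) {
    prof <- a[21, 21, ]
    sum(prof >= max(prof) / 2) * 0.4
  }
  expect_lte(fwhm_z(r$x), fwhm_z(y) / 2)
})

test_that("interior flux is conserved through deconvolution", {
  sc <- ball_scene(r = 3, conc = 2, background = 0.05)
  st <- render_stack(sc, gauss_psf(12), noise = NULL, sampling = test_sampling)
  dec <- suppressWarnings(
    deconvolve_mle(st, gauss_psf(12),
                   deconv_settings(background_estimate = 0.05)))
  expect_equal(sum(dec$data) * voxel_volume(dec), 2 * 4 / 3 * pi * 27,
               tolerance = 0.01)
  expect_true(all(dec$data >= 0))
})

test_that("the Poisson log-likelihood is monotone on a noise-free fixture", {
  sc <- ball_scene(r = 2.5, conc = 3, field = c(12, 12, 10), background = 0.02)
  st <- render_stack(sc, gauss_psf(10), noise = NULL, sampling = test_sampling)
  kern <- gauss_psf(10)$per_brick_kernels[[1]]
  r <- rl_deconvolve(stack_channel(st, 1), kern,
                     deconv_settings(max_iterations = 30,
                                     background_estimate = 0.02),
                     trace = TRUE)
  expect_gte(length(r$loglik), 25)
  expect_true(all(diff(r$loglik) > -1e-8 * abs(r$loglik[-1])))
})

test_that("one extra iteration after convergence changes the estimate below the threshold", {
  sc <- ball_scene(r = 2.5, conc = 3, field = c(12, 12, 10))
  st <- render_stack(sc, gauss_psf(10), noise = NULL, sampling = test_sampling)
  kern <- gauss_psf(10)$per_brick_kernels[[1]]
  set <- deconv_settings(quality_change_threshold = 0.01,
                         max_iterations = 200)
  r <- rl_deconvolve(stack_channel(st, 1), kern, set)
  expect_true(r$converged)
  frozen <- deconv_settings(quality_change_threshold = 1e-12,
                            max_iterations = r$iterations + 1L)
  r1 <- rl_deconvolve(stack_channel(st, 1), kern, frozen)
  rel <- sqrt(sum((r1$x - r$x)^2)) / sqrt(sum(r$x^2))
  expect_lt(rel, set$quality_change_threshold)
})

test_that("deconvolution input contracts are enforced", {
  sc <- ball_scene(r = 2.5, conc = 3, field = c(12, 12, 10))
  st <- render_stack(sc, gauss_psf(10), noise = NULL, sampling = test_sampling)
  bad <- st; bad$data[1] <- NaN
  expect_error(deconvolve_mle(bad, gauss_psf(10)), "non-finite")
  short <- psf_model(optics_settings(grid_sampling = test_sampling), 5,
                     mode = "one")
  expect_error(deconvolve_mle(st, short), "span")
  expect_warning(deconvolve_mle(st, gauss_psf(10),
                                deconv_settings(max_iterations = 2)),
                 "max_iterations")
})
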