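test_that("a uniform ball renders to its analytic volume integral under identity optics", {
  sc <- ball_scene(r = 3, conc = 2)
  st <- render_stack(sc, delta_psf(12), noise = NULL, sampling = test_sampling)
  tot <- sum(st$data) * voxel_volume(st)
  expect_equal(tot, 2 * 4 / 3 * pi * 27, tolerance = 0.01)
})

test_that("blurring with a unit-mass PSF conserves the total signal", {
  sc <- ball_scene(r = 3, conc = 2)
  st0 <- render_stack(sc, delta_psf(12), noise = NULL, sampling = test_sampling)
  st1 <- render_stack(sc, gauss_psf(12), noise = NULL, sampling = test_sampling)
  expect_equal(sum(st1$data), sum(st0$data), tolerance = 0.01)
})

test_that("rendering is bit-reproducible for identical (scene, psf, noise, seed)", {
  sc <- sample_scene("constant_concentration", c(cellA = 3), seed = 4,
                     field_size = c(28, 28, 14))
  a <- render_stack(sc, gauss_psf(14), noise_model(), test_sampling, seed = 9)
  b <- render_stack(sc, gauss_psf(14), noise_model(), test_sampling, seed = 9)
  expect_identical(a$data, b$data)
  c2 <- render_stack(sc, gauss_psf(14), noise_model(), test_sampling, seed = 10)
  expect_false(identical(a$data, c2$data))
})

test_that("doubling every truth concentration doubles the above-background flux", {
  sc <- sample_scene("constant_concentration", c(cellA = 3), seed = 4,
                     field_size = c(28, 28, 14))
  sc2 <- sc
  sc2$nuclei$conc_yfp <- 2 * sc$nuclei$conc_yfp
  nm <- noise_model()
  s1 <- render_stack(sc, gauss_psf(14), nm, test_sampling, seed = 3)
  s2 <- render_stack(sc2, gauss_psf(14), nm, test_sampling, seed = 3)
  above <- function(s) sum(s$data - nm$offset - sc$background_level)
  expect_equal(above(s2) / above(s1), 2, tolerance = 0.02)
})

test_that("the oracle renderer reconstructs every expected voxel from the truth record", {
  sc <- sample_scene("constant_concentration", c(cellA = 3), seed = 8,
                     field_size = c(28, 28, 14))
  st <- render_stack(sc, delta_psf(14), noise = NULL, sampling = test_sampling)
  oracle <- render_expected(sc, test_sampling)
  expect_equal(st$data, oracle$data, tolerance = 1e-12)
  # per-nucleus masked integral matches concentration x volume within 1%
  for (i in seq_len(nrow(sc$nuclei))) {
    nu <- sc$nuclei[i, ]
    cv <- nucquant:::ellipsoid_coverage(nu, test_sampling, dim_stack(oracle))
    masked <- sum((oracle$data[, , , 1][cv$index] - sc$background_level)) *
      voxel_volume(oracle)
    expect_equal(masked, nu$conc_yfp * nu$volume, tolerance = 0.01)
  }
})

test_that("truth-masked sums of a noisy rendered stack rank-correlate with truth totals", {
  sc <- sample_scene("cortex", c(neuron = 6, glia = 6), seed = 1)
  st <- render_stack(sc, NULL, noise_model(), test_sampling, seed = 1)
  arr <- stack_channel(st, 1)
  sums <- vapply(seq_len(nrow(sc$nuclei)), function(i) {
    cv <- nucquant:::ellipsoid_coverage(sc$nuclei[i, ], test_sampling,
                                        dim_stack(st))
    sum(arr[cv$index])
  }, 0)
  truth <- sc$nuclei$conc_yfp * sc$nuclei$volume
  expect_gt(cor(sums, truth, method = "spearman"), 0.99)
})
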