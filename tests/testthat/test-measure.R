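test_that("a uniform ball measures its analytic volume and total", {
  sc <- ball_scene(r = 3, conc = 50)
  st <- render_stack(sc, delta_psf(12), noise = NULL, sampling = test_sampling)
  seg <- segment_nuclei(st, threshold = 1, min_volume = 10)
  m <- measure_nuclei(st, seg)
  vtrue <- 4 / 3 * pi * 27
  expect_equal(m$volume, vtrue, tolerance = 0.02)
  expect_equal(m$total_signal, 50 * vtrue, tolerance = 0.01)
  expect_equal(m$concentration, 50, tolerance = 0.02)
  expect_equal(unname(c(m$centroid_x, m$centroid_y, m$centroid_z)),
               c(8, 8, 6), tolerance = 0.05)
})

test_that("measurements are invariant under label renumbering", {
  st <- make_mask_stack(list(c(25, 25, 20), c(55, 55, 20)))
  seg <- segment_nuclei(st, threshold = 5, min_volume = 20)
  m1 <- measure_nuclei(st, seg)
  perm <- seg
  perm$label_map[] <- c(0L, 2L, 1L)[perm$label_map + 1L]  # swap 1 <-> 2
  m2 <- measure_nuclei(st, perm)
  o1 <- m1[order(m1$centroid_x), -1]
  o2 <- m2[order(m2$centroid_x), -1]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("the ellipsoid fast formula is exact for ellipsoids and biased for cubes", {
  expect_equal(ellipsoid_volume(pi * 9, 6), 4 / 3 * pi * 27, tolerance = 1e-12)
  expect_equal(ellipsoid_volume(pi * 12, 4), 32 * pi, tolerance = 1e-12)
  expect_equal(ellipsoid_volume(pi * 12, 4), 4 / 3 * pi * 4 * 3 * 2,
               tolerance = 1e-12)
  # cube of side 4: formula gives 2/3 * 16 * 4 = 42.67 vs true 64 (-33%)
  expect_equal(ellipsoid_volume(16, 4) / 64 - 1, -1 / 3, tolerance = 1e-12)
  expect_error(ellipsoid_volume(-1, 2), "positive")
  expect_error(ellipsoid_volume(3, 0), "positive")
})

test_that("fast volume matches the voxel volume for a rendered axis-aligned ellipsoid", {
  iso <- c(0.2, 0.2, 0.2)
  sc <- ball_scene(r = 3, conc = 10, field = c(18, 18, 14))
  sc$nuclei$ax_a <- 4; sc$nuclei$ax_b <- 3; sc$nuclei$ax_c <- 2.4
  sc$nuclei$volume <- 4 / 3 * pi * 4 * 3 * 2.4
  st <- render_stack(sc, delta_psf(14, iso), noise = NULL, sampling = iso)
  seg <- segment_nuclei(st, threshold = 5, min_volume = 10)  # half plateau
  fast <- measure_ellipsoid_fast(st, seg)
  full <- measure_nuclei(st, seg, volume_method = "voxel_count")
  expect_equal(fast$volume, full$volume, tolerance = 0.05)
  expect_match(fast$qc, "fast_volume")
  expect_equal(fast$total_signal, full$total_signal)
})

test_that("the fast volume overestimates for an ellipsoid tilted out of the xy plane", {
  # analytic mask of an ellipsoid rotated 45 degrees about x
  dims <- c(70, 70, 36)
  a <- 4; b <- 2; cc <- 2
  th <- pi / 4
  ctr <- c(35, 35, 18)
  arr <- array(0, dims)
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2])) {
    yy <- (y - ctr[2]) * test_sampling[2]
    zz <- (z - ctr[3]) * test_sampling[3]
    v <- yy * cos(th) + zz * sin(th)
    w <- -yy * sin(th) + zz * cos(th)
    xs <- (seq_len(dims[1]) - ctr[1]) * test_sampling[1]
    arr[, y, z] <- 10 * ((xs / a)^2 + (v / b)^2 + (w / cc)^2 <= 1)
  }
  st <- image_stack(arr, test_sampling)
  seg <- segment_nuclei(st, threshold = 5, min_volume = 5)
  fast <- measure_ellipsoid_fast(st, seg)
  full <- measure_nuclei(st, seg, volume_method = "voxel_count")
  expect_gt(fast$volume, full$volume * 1.05)
})

test_that("fast and full totals rank-correlate on a cycling population", {
  run <- small_cycling_run()
  fast <- measure_ellipsoid_fast(run$deconvolved, run$segmentation)
  full <- run$measurements
  expect_gt(cor(fast$total_signal, full$total_signal, method = "spearman"),
            0.99)
})

test_that("per-nucleus concentration is nearly constant end-to-end on the constant preset", {
  run <- small_constant_run()
  conc <- get_channel(run$measurements, "yfp")$concentration
  expect_lt(sd(conc) / mean(conc), 0.10)
})

test_that("measurement tables round-trip through CSV", {
  run <- small_constant_run()
  f <- tempfile(fileext = ".csv")
  write_measurements(run$measurements, f)
  back <- read_measurements(f)
  expect_equal(back$total_signal, run$measurements$total_signal,
               tolerance = 1e-12)
  expect_s3_class(back, "nucleus_measurements")
})
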