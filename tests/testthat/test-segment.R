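test_that("background estimate brackets the true floor and sits below object interiors", {
  dims <- c(60, 60, 30)
  arr <- array(10, dims)
  xs <- (seq_len(dims[1]) - 30)^2
  zs <- (seq_len(dims[3]) - 15)^2
  ball <- outer(outer(xs, xs, `+`), zs * 4, `+`) <= 64
  arr[ball] <- 60
  arr <- arr + array(rnorm(prod(dims), 0, 0.5), dims)
  bg <- estimate_background(image_stack(arr, test_sampling))
  expect_gt(bg$threshold, 10 - 0.5)
  expect_lt(bg$threshold, 60)
  expect_equal(bg$mode, 10, tolerance = 0.05)
})

test_that("the estimate matches the Gaussian closed form and is scale-equivariant", {
  set.seed(1)
  arr <- array(rnorm(6e4, 100, 5), c(50, 40, 30))
  bg <- estimate_background(image_stack(arr, test_sampling))
  # mode ~ 100, scaled MAD ~ sigma: mode + 3 MAD in [100, ~115]
  expect_gt(bg$threshold, 100)
  expect_lt(bg$threshold, 117)
  bg10 <- estimate_background(image_stack(arr * 10, test_sampling))
  expect_equal(bg10$threshold / bg$threshold, 10, tolerance = 0.02)
  expect_error(estimate_background(image_stack(array(1, c(4, 4, 4)),
                                               test_sampling)),
               "constant")
})

test_that("well-separated interior balls are kept; face-touching ones are rejected as truncated", {
  st <- make_mask_stack(list(c(25, 25, 20), c(55, 55, 20)))
  seg <- segment_nuclei(st, threshold = 5, min_volume = 20)
  expect_equal(seg$n_kept, 2L)
  expect_equal(nrow(seg$rejected), 0L)
  st2 <- make_mask_stack(list(c(40, 40, 1)))       # centred on the z = 1 face
  seg2 <- segment_nuclei(st2, threshold = 5, min_volume = 20)
  expect_equal(seg2$n_raw, 1L)
  expect_equal(seg2$n_kept, 0L)
  expect_equal(seg2$rejected$reason, "truncated")
})

test_that("no kept label touches any stack face", {
  run <- small_constant_run()
  lab <- run$segmentation$label_map
  d <- dim(lab)
  faces <- c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
             lab[, , 1], lab[, , d[3]])
  expect_true(all(faces == 0L))
  expect_identical(sort(unique(as.integer(lab[lab > 0]))),
                   seq_len(run$segmentation$n_kept))
})

test_that("oversized components are rejected as merged", {
  dims <- c(110, 110, 40)
  st <- make_mask_stack(list(c(25, 25, 20), c(55, 25, 20), c(85, 25, 20)),
                        dims = dims)
  big <- make_mask_stack(list(c(55, 80, 20)), r = 3.8, dims = dims)
  st$data <- st$data + big$data
  seg <- segment_nuclei(st, threshold = 5, min_volume = 20,
                        merged_multiple = 2.5)
  expect_equal(seg$n_kept, 3L)
  expect_true("merged" %in% seg$rejected$reason)
})

test_that("internal holes are filled slice by slice", {
  arr <- array(0, c(30, 30, 10))
  arr[10:20, 10:20, 3:8] <- 10
  arr[14:16, 14:16, 4:7] <- 0                      # hollow core
  st <- image_stack(arr, test_sampling)
  seg <- segment_nuclei(st, threshold = 5, min_volume = 1)
  expect_equal(seg$n_kept, 1L)
  expect_equal(sum(seg$label_map > 0), 11 * 11 * 6)
})

test_that("an empty field warns instead of erroring", {
  arr <- array(rnorm(8000, 1, 0.01), c(20, 20, 20))
  st <- image_stack(arr, test_sampling)
  expect_warning(seg <- segment_nuclei(st, threshold = max(arr) * 1.01,
                                       min_volume = 50),
                 "no components")
  expect_equal(seg$n_kept, 0L)
})
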