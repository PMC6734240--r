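meas_df <- function(totals, volumes, channel = "yfp") {
  data.frame(label = seq_along(totals), channel = channel,
             total_signal = totals, volume = volumes,
             concentration = totals / volumes)
}

test_that("a noiseless proportional cloud fits exactly through the origin", {
  V <- c(100, 150, 220, 300, 410, 520)
  fit <- fit_constant_concentration(meas_df(5 * V, V), n_boot = 200)
  expect_equal(fit$slope, 5)
  expect_equal(fit$r2_through_origin, 1)
  expect_equal(fit$volume_concentration_spearman, 0)
})

test_that("quadratic totals are flagged by the constancy diagnostic", {
  V <- seq(100, 500, length.out = 20)
  fit <- fit_constant_concentration(meas_df(0.01 * V^2, V), n_boot = 200)
  expect_gt(fit$volume_concentration_spearman, 0.99)
})

test_that("the through-origin slope is scale-equivariant", {
  set.seed(3)
  V <- runif(15, 100, 400)
  TT <- 3 * V * (1 + rnorm(15, 0, 0.05))
  f0 <- fit_constant_concentration(meas_df(TT, V), n_boot = 100)
  fT <- fit_constant_concentration(meas_df(7 * TT, V), n_boot = 100)
  fV <- fit_constant_concentration(meas_df(TT, 7 * V), n_boot = 100)
  expect_equal(fT$slope, 7 * f0$slope, tolerance = 1e-12)
  expect_equal(fV$slope, f0$slope / 7, tolerance = 1e-12)
})

test_that("equal volumes keep the fit but disable the diagnostic with a warning", {
  expect_warning(
    fit <- fit_constant_concentration(meas_df(c(10, 11, 9, 10, 10),
                                              rep(50, 5)), n_boot = 100),
    "volumes equal")
  expect_true(is.finite(fit$slope))
  expect_true(is.na(fit$volume_concentration_spearman))
})

test_that("bootstrap CIs are seed-reproducible and widen as n shrinks", {
  set.seed(12)
  V <- runif(100, 100, 400)
  TT <- 3 * V * (1 + rnorm(100, 0, 0.15))
  w <- vapply(c(10, 30, 100), function(n) {
    f <- fit_constant_concentration(meas_df(TT[1:n], V[1:n]),
                                    n_boot = 500, seed = 7)
    diff(f$slope_ci)
  }, 0)
  expect_true(w[1] > w[2] && w[2] > w[3])
  f1 <- fit_constant_concentration(meas_df(TT, V), n_boot = 300, seed = 9)
  f2 <- fit_constant_concentration(meas_df(TT, V), n_boot = 300, seed = 9)
  expect_identical(f1$slope_ci, f2$slope_ci)
})

test_that("concentration ratios behave like ratios", {
  a <- meas_df(rep(10, 5), rep(2, 5))
  r <- concentration_ratio(a, a, n_boot = 100)
  expect_equal(r$ratio, 1)
  expect_equal(unname(diff(r$ratio_ci)), 0)
  b <- meas_df(c(30, 32, 28, 31), rep(2, 4))
  r_ab <- concentration_ratio(a, b, n_boot = 100)
  r_ba <- concentration_ratio(b, a, n_boot = 100)
  expect_equal(r_ab$ratio, 1 / r_ba$ratio, tolerance = 1e-12)
  expect_equal(r_ab$percent, 100 * r_ab$ratio)
  expect_error(concentration_ratio(a$concentration, rep(0, 4)), "zero")
  expect_error(concentration_ratio(a$concentration[1:2], b$concentration),
               ">= 3")
})

test_that("ploidy peaks recover the 1:2 doubling and are scale invariant", {
  set.seed(2)
  totals <- c(rnorm(160, 1, 0.05), rnorm(90, 2, 0.1))
  p <- ploidy_peaks(totals, n_boot = 200, seed = 3)
  expect_equal(p$peak_positions[1], 1)
  expect_equal(p$second_peak, 2, tolerance = 0.05)
  p2 <- ploidy_peaks(totals * 137.5, n_boot = 200, seed = 3)
  expect_equal(p2$peak_positions, p$peak_positions, tolerance = 1e-6)
  # normalization is idempotent: renormalizing normalized positions is a no-op
  expect_equal(p$peak_positions / p$peak_positions[1], p$peak_positions)
})

test_that("a single population yields a warning and no second peak", {
  set.seed(4)
  expect_warning(p <- ploidy_peaks(rnorm(200, 5, 0.2), n_boot = 50),
                 "second_peak|peaks")
  expect_true(is.na(p$second_peak))
})

test_that("Spearman rho matches hand arithmetic and the brute-force oracle", {
  # d^2 = (1,1,1,1,0): rho = 1 - 6*4/(5*24) = 0.8
  r <- spearman_correlation(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)
  expect_equal(r$rho, oracle_rho(1:5, c(2, 1, 4, 3, 5)))
  expect_equal(spearman_correlation(1:6, (1:6)^3)$rho, 1)
  set.seed(5)
  for (n in 4:8) {
    x <- rnorm(n); y <- rnorm(n)
    r <- spearman_correlation(x, y)
    expect_equal(r$rho, oracle_rho(x, y), tolerance = 1e-12)
    expect_equal(r$p_value, oracle_exact_p(x, y), tolerance = 1e-12)
  }
  # ties: mid-rank rho agrees with the reference implementation
  x <- c(1, 2, 2, 3, 4, 4, 5); y <- c(2, 2, 3, 5, 4, 6, 6)
  expect_equal(spearman_correlation(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(6)
  x <- rexp(30); y <- x + rnorm(30, 0, 0.5)
  r0 <- spearman_correlation(x, y)$rho
  expect_equal(spearman_correlation(log(x), y)$rho, r0)
  expect_equal(spearman_correlation(x, y^3)$rho, r0)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:2, 2:1), "n >= 3")
})

gel_fixture <- function(bands, bg = 50, size = c(60, 80)) {
  g <- matrix(bg, size[1], size[2])
  for (b in bands) g[b$y0:b$y1, b$x0:b$x1] <- g[b$y0:b$y1, b$x0:b$x1] + b$amp
  g
}

test_that("densitometry volumes are exact on constructed bands", {
  rects <- data.frame(lane = c("a", "a"), band = c("target", "loading"),
                      x0 = c(10, 10), x1 = c(19, 19),
                      y0 = c(10, 30), y1 = c(14, 34))
  g <- gel_fixture(list(list(x0 = 10, x1 = 19, y0 = 10, y1 = 14, amp = 100),
                        list(x0 = 10, x1 = 19, y0 = 30, y1 = 34, amp = 100)))
  r <- blot_volume(g, rects)
  expect_equal(unname(r$lane_volumes["a"]), 100 * 50)
  # uniform image: all volumes zero
  r0 <- blot_volume(matrix(7, 60, 80), rects)
  expect_equal(unname(r0$lane_volumes["a"]), 0)
})

test_that("densitometry recovers an injected 1.6x fold change, offset-invariantly", {
  mk <- function(bg) gel_fixture(list(
    list(x0 = 10, x1 = 19, y0 = 10, y1 = 14, amp = 100),   # ref target
    list(x0 = 10, x1 = 19, y0 = 30, y1 = 34, amp = 80),    # ref loading
    list(x0 = 40, x1 = 49, y0 = 10, y1 = 14, amp = 160),   # cond target
    list(x0 = 40, x1 = 49, y0 = 30, y1 = 34, amp = 80)),   # cond loading
    bg = bg)
  rects <- data.frame(
    lane = c("starved", "starved", "proliferating", "proliferating"),
    band = c("target", "loading", "target", "loading"),
    x0 = c(10, 10, 40, 40), x1 = c(19, 19, 49, 49),
    y0 = c(10, 30, 10, 30), y1 = c(14, 34, 14, 34))
  r <- blot_volume(mk(50), rects, reference = "starved")
  expect_equal(unname(r$fold_change["starved"]), 1)
  expect_equal(unname(r$fold_change["proliferating"]), 1.6, tolerance = 0.02)
  r2 <- blot_volume(mk(500), rects, reference = "starved")
  expect_equal(r2$fold_change, r$fold_change, tolerance = 1e-12)
})

test_that("densitometry geometry contracts are enforced", {
  g <- matrix(1, 20, 20)
  near_edge <- data.frame(lane = "a", band = "target",
                          x0 = 1, x1 = 5, y0 = 5, y1 = 8)
  expect_error(blot_volume(g, near_edge), "frame")
  overlap <- data.frame(lane = c("a", "b"), band = c("target", "target"),
                        x0 = c(5, 7), x1 = c(10, 12),
                        y0 = c(5, 6), y1 = c(10, 11))
  expect_error(blot_volume(g, overlap), "overlap")
})
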