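#' Select one channel from a measurements table
#'
#' @param measurements a `nucleus_measurements` data frame.
#' @param channel channel name; default: the first channel present.
#' @return The measurement rows of that channel.
#' @export
get_channel <- function(measurements, channel = NULL) {
  if (!is.data.frame(measurements)) stopf("expected a measurements data frame")
  if (is.null(channel)) channel <- measurements$channel[1]
  out <- measurements[measurements$channel == channel, , drop = FALSE]
  if (!nrow(out)) stopf("no measurements for channel '%s'", channel)
  out
}

boot_ci <- function(stat, n, n_boot, seed, conf = 0.95) {
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) stat(sample.int(n, n, replace = TRUE)),
           0)
  })
  reps <- reps[is.finite(reps)]
  a <- (1 - conf) / 2
  c(quantile(reps, a, names = FALSE), quantile(reps, 1 - a, names = FALSE))
}

#' Constant-concentration fit of total signal on nuclear volume
#'
#' Formalizes the radial iso-concentration picture: if a population keeps a
#' fixed nuclear concentration, per-cell total signal is proportional to
#' nuclear volume. Fits the through-origin least squares line
#' \eqn{slope = \sum TV / \sum V^2} (the population concentration in
#' a.u./µm³), with a seeded bootstrap CI, the uncentered through-origin
#' \eqn{R^2}, a free-intercept fit as a diagnostic, and the Spearman
#' correlation between per-cell concentration and volume — the constancy
#' diagnostic, which is near 0 when concentration is volume-independent
#' and near 1 for, e.g., totals growing like volume squared.
#'
#' @param measurements a `nucleus_measurements` data frame (one channel is
#'   selected), or anything with `total_signal` and `volume` columns.
#' @param channel channel to fit (default: first present).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return A `concentration_fit` object: `slope`, `slope_ci`,
#'   `r2_through_origin`, `per_cell_concentrations`,
#'   `volume_concentration_spearman` (with its bootstrap CI),
#'   `free_fit` (intercept/slope), `n`.
#' @export
fit_constant_concentration <- function(measurements, channel = NULL,
                                       n_boot = 2000, seed = 1,
                                       conf = 0.95) {
  m <- get_channel(measurements, channel)
  TT <- m$total_signal; V <- m$volume
  if (length(TT) < 5) stopf("need at least 5 measurements")
  slope <- sum(TT * V) / sum(V^2)
  r2 <- 1 - sum((TT - slope * V)^2) / sum(TT^2)
  conc <- TT / V
  const_vol <- (max(V) - min(V)) < 1e-12 * max(abs(V), 1)
  rho <- NA_real_; rho_ci <- c(NA_real_, NA_real_)
  if (const_vol) {
    warnf("all volumes equal: the concentration-vs-volume diagnostic is unavailable")
  } else if (max(conc) - min(conc) < 1e-12 * max(abs(conc))) {
    rho <- 0; rho_ci <- c(0, 0)   # exactly constant concentration
  } else {
    rho <- spearman_rho(conc, V)
    rho_ci <- boot_ci(function(i) spearman_rho(conc[i], V[i]),
                      length(V), n_boot, seed + 1L, conf)
  }
  slope_ci <- boot_ci(function(i) sum(TT[i] * V[i]) / sum(V[i]^2),
                      length(V), n_boot, seed, conf)
  free <- if (const_vol) c(intercept = NA_real_, slope = NA_real_) else
    setNames(coef(lm(TT ~ V)), c("intercept", "slope"))
  structure(list(slope = slope, slope_ci = slope_ci,
                 r2_through_origin = r2,
                 per_cell_concentrations = conc,
                 volume_concentration_spearman = rho,
                 spearman_ci = rho_ci, free_fit = free,
                 n = length(V), conf = conf,
                 totals = TT, volumes = V),
            class = "concentration_fit")
}

#' @export
print.concentration_fit <- function(x, ...) {
  cat(sprintf("<concentration_fit> n = %d nuclei\n", x$n))
  cat(sprintf("  concentration (through-origin slope): %.4g a.u./um^3  [%.4g, %.4g] %g%% CI\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], 100 * x$conf))
  cat(sprintf("  through-origin R^2: %.4f\n", x$r2_through_origin))
  cat(sprintf("  concentration-vs-volume Spearman rho: %.3f  [%.3f, %.3f]\n",
              x$volume_concentration_spearman, x$spearman_ci[1],
              x$spearman_ci[2]))
  cat(sprintf("  free-intercept diagnostic: intercept %.4g, slope %.4g\n",
              x$free_fit[1], x$free_fit[2]))
  invisible(x)
}

#' @export
coef.concentration_fit <- function(object, ...) c(slope = object$slope)

#' @export
#' @importFrom graphics abline plot points
plot.concentration_fit <- function(x, ...) {
  plot(x$volumes, x$totals, xlab = "nuclear volume (um^3)",
       ylab = "total signal (a.u.)", xlim = c(0, max(x$volumes) * 1.05),
       ylim = c(0, max(x$totals) * 1.05), ...)
  abline(0, x$slope, lty = 2)
  invisible(x)
}

#' Concentration ratio between two populations
#'
#' Ratio of mean per-nucleus concentrations of two groups (and, separately,
#' of mean total signals), with seeded bootstrap CIs and both orientations
#' (a/b and its percentage, plus b/a).
#'
#' @param group_a,group_b `nucleus_measurements` data frames (single
#'   channel), or numeric vectors of per-nucleus concentrations.
#' @param n_boot,seed,conf bootstrap settings.
#' @return A `concentration_ratio` object: `ratio` (mean-concentration
#'   a/b), `ratio_ci`, `percent` (100 x a/b) with `percent_ci`,
#'   `ratio_total`, `inverse`, group sizes.
#' @export
concentration_ratio <- function(group_a, group_b, n_boot = 2000, seed = 1,
                                conf = 0.95) {
  conc_of <- function(g) if (is.data.frame(g)) g$concentration else as.numeric(g)
  tot_of <- function(g) if (is.data.frame(g)) g$total_signal else as.numeric(g)
  ca <- conc_of(group_a); cb <- conc_of(group_b)
  if (length(ca) < 3 || length(cb) < 3) stopf("each group needs >= 3 nuclei")
  if (mean(cb) == 0 || mean(ca) == 0) stopf("zero mean concentration in a group")
  ratio <- mean(ca) / mean(cb)
  ta <- tot_of(group_a); tb <- tot_of(group_b)
  seeds <- derive_seeds(seed, 2)
  reps <- with_seed(seeds[1], vapply(seq_len(n_boot), function(b)
    mean(sample(ca, replace = TRUE)) / mean(sample(cb, replace = TRUE)), 0))
  a <- (1 - conf) / 2
  ci <- c(quantile(reps, a, names = FALSE), quantile(reps, 1 - a, names = FALSE))
  structure(list(ratio = ratio, ratio_ci = ci,
                 percent = 100 * ratio, percent_ci = 100 * ci,
                 ratio_total = mean(ta) / mean(tb),
                 inverse = 1 / ratio,
                 n_a = length(ca), n_b = length(cb), conf = conf),
            class = "concentration_ratio")
}

#' @export
print.concentration_ratio <- function(x, ...) {
  cat(sprintf("<concentration_ratio> n = %d vs %d nuclei\n", x$n_a, x$n_b))
  cat(sprintf("  mean-concentration ratio a/b: %.3f  (%.1f%%)  [%.1f%%, %.1f%%] %g%% CI\n",
              x$ratio, x$percent, x$percent_ci[1], x$percent_ci[2],
              100 * x$conf))
  cat(sprintf("  b/a: %.3f;  mean-total ratio a/b: %.3f\n",
              x$inverse, x$ratio_total))
  invisible(x)
}

find_peaks <- function(y, prominence_frac) {
  n <- length(y)
  locmax <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  prom <- vapply(locmax, function(i) {
    lmin <- rmin <- y[i]
    j <- i
    while (j > 1 && y[j - 1] <= y[i]) { j <- j - 1; lmin <- min(lmin, y[j]) }
    j <- i
    while (j < n && y[j + 1] <= y[i]) { j <- j + 1; rmin <- min(rmin, y[j]) }
    y[i] - max(lmin, rmin)
  }, 0)
  locmax[prom >= prominence_frac * max(y)]
}

#' DNA-content (ploidy) peak calling
#'
#' Validates the volumetric pipeline against the DNA-doubling control: the
#' per-nucleus integrated DNA-stain totals of a cycling population form
#' peaks at content ratio 2 (G1 vs G2). A Gaussian kernel density estimate
#' (Silverman's rule by default) is scanned for local maxima above a
#' prominence floor; peak positions are normalized by the lowest peak, so
#' the G2 peak is expected at 2.
#'
#' @param totals per-nucleus DNA-channel totals (a.u.); a warning is issued
#'   below 50 nuclei.
#' @param bandwidth KDE bandwidth in a.u. (`NULL` = Silverman).
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   density maximum.
#' @param n_boot bootstrap resamples over nuclei for the peak-ratio CI.
#' @param seed,conf bootstrap settings.
#' @return A `ploidy_result`: `peak_positions` (normalized, ascending,
#'   first = 1), `second_peak`, `peak_ratio_ci`, `bandwidth`,
#'   `raw_positions`, `density`.
#' @export
ploidy_peaks <- function(totals, bandwidth = NULL, prominence_frac = 0.05,
                         n_boot = 1000, seed = 1, conf = 0.95) {
  totals <- as.numeric(totals)
  if (length(totals) < 50)
    warnf("only %d nuclei: ploidy peak calling is unreliable below 50",
          length(totals))
  second_of <- function(v) {
    d <- density(v, bw = bandwidth %||% "nrd0", n = 512)
    pk <- find_peaks(d$y, prominence_frac)
    if (length(pk) < 2) return(c(NA_real_, NA_real_))
    pos <- sort(d$x[pk])
    c(pos[1], pos[2])
  }
  d <- density(totals, bw = bandwidth %||% "nrd0", n = 512)
  pk <- find_peaks(d$y, prominence_frac)
  raw <- sort(d$x[pk])
  if (length(raw) < 2)
    warnf("fewer than 2 density peaks: single population? second_peak is undefined")
  normalized <- if (length(raw)) raw / raw[1] else numeric()
  second <- if (length(raw) >= 2) normalized[2] else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (length(raw) >= 2) {
    reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      p <- second_of(sample(totals, replace = TRUE))
      p[2] / p[1]
    }, 0))
    reps <- reps[is.finite(reps)]
    a <- (1 - conf) / 2
    if (length(reps) >= n_boot / 2)
      ci <- c(quantile(reps, a, names = FALSE),
              quantile(reps, 1 - a, names = FALSE))
  }
  structure(list(peak_positions = normalized, second_peak = second,
                 peak_ratio_ci = ci, bandwidth = d$bw,
                 raw_positions = raw, density = d, n = length(totals)),
            class = "ploidy_result")
}

#' @export
print.ploidy_result <- function(x, ...) {
  cat(sprintf("<ploidy_result> n = %d nuclei, KDE bandwidth %.4g a.u.\n",
              x$n, x$bandwidth))
  cat(sprintf("  normalized peaks: %s\n",
              paste(sprintf("%.3f", x$peak_positions), collapse = ", ")))
  if (is.finite(x$second_peak))
    cat(sprintf("  second peak at %.3f  [%.3f, %.3f]\n", x$second_peak,
                x$peak_ratio_ci[1], x$peak_ratio_ci[2]))
  invisible(x)
}

#' @export
#' @importFrom graphics rug
plot.ploidy_result <- function(x, ...) {
  plot(x$density, main = "integrated DNA signal per nucleus", ...)
  rug(x$raw_positions, col = 2, lwd = 2)
  invisible(x)
}

spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rx <- rx - mean(rx); ry <- ry - mean(ry)
  den <- sqrt(sum(rx^2) * sum(ry^2))
  if (den == 0) return(NA_real_)
  sum(rx * ry) / den
}

#' Spearman rank correlation with small-sample exact p-values
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' The two-sided p-value is computed by full enumeration of all
#' permutations for n <= 8, by a seeded Monte-Carlo permutation test for
#' 8 < n <= 50, and by the t approximation above.
#'
#' @param x,y paired per-nucleus totals (n >= 3).
#' @param channel_pair labels for the two variables.
#' @param n_perm Monte-Carlo permutations.
#' @param seed permutation seed.
#' @return A `correlation_result`: `rho`, `n`, `p_value`, `method`,
#'   `channel_pair`.
#' @export
spearman_correlation <- function(x, y, channel_pair = c("x", "y"),
                                 n_perm = 10000, seed = 1) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y must be paired")
  n <- length(x)
  if (n < 3) stopf("need n >= 3 pairs")
  if (max(x) == min(x) || max(y) == min(y))
    stopf("rho is undefined for a constant variable")
  rho <- spearman_rho(x, y)
  if (n <= 8) {
    perms <- all_permutations(n)
    ry <- rank(y)
    rhos <- apply(perms, 1, function(p) spearman_rho(rank(x), ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact enumeration"
  } else if (n <= 50) {
    rhos <- with_seed(seed, vapply(seq_len(n_perm), function(b)
      spearman_rho(x, y[sample.int(n)]), 0))
    p <- (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / (n_perm + 1)
    method <- "Monte-Carlo permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, n = n, p_value = min(p, 1), method = method,
                 channel_pair = channel_pair),
            class = "correlation_result")
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s vs %s: Spearman rho = %.3f (n = %d)\n",
              x$channel_pair[1], x$channel_pair[2], x$rho, x$n))
  cat(sprintf("  two-sided p = %.4g (%s)\n", x$p_value, x$method))
  invisible(x)
}

#' Gel densitometry by the rectangle-volume method
#'
#' Integrates band intensity over user-drawn rectangles with local
#' background subtraction: the background is the mean intensity of a
#' `frame_width`-pixel frame around each rectangle, times the rectangle
#' area. Per lane, the target-band volume is normalized by the
#' loading-control band; fold changes are relative to a named reference
#' lane (whose fold change is 1 by construction).
#'
#' @param gel_image numeric matrix (rows = y, columns = x).
#' @param rectangles data frame with columns `lane`, `band` ("target" or
#'   "loading"), `x0`, `x1`, `y0`, `y1` (1-based, inclusive; x = column).
#' @param frame_width local-background frame width in pixels.
#' @param reference lane name whose normalized volume defines fold change 1
#'   (default: first lane).
#' @return A `densitometry_result`: per-lane `lane_volumes`,
#'   `local_background`, `normalized`, `fold_change`.
#' @export
blot_volume <- function(gel_image, rectangles, frame_width = 2,
                        reference = NULL) {
  stopifnot(is.matrix(gel_image))
  req <- c("lane", "band", "x0", "x1", "y0", "y1")
  if (!all(req %in% names(rectangles)))
    stopf("rectangles needs columns: %s", paste(req, collapse = ", "))
  nr <- nrow(gel_image); ncol_ <- ncol(gel_image)
  f <- frame_width
  for (i in seq_len(nrow(rectangles))) {
    r <- rectangles[i, ]
    if (r$x0 > r$x1 || r$y0 > r$y1 || r$x0 < 1 || r$y0 < 1 ||
        r$x1 > ncol_ || r$y1 > nr)
      stopf("rectangle %d is not inside the image", i)
    if (r$x0 - f < 1 || r$y0 - f < 1 || r$x1 + f > ncol_ || r$y1 + f > nr)
      stopf("local-background frame of rectangle %d exits the image", i)
    for (j in seq_len(i - 1)) {
      q <- rectangles[j, ]
      if (r$x0 <= q$x1 && q$x0 <= r$x1 && r$y0 <= q$y1 && q$y0 <= r$y1)
        stopf("rectangles %d and %d overlap", j, i)
    }
  }
  vol <- bg <- numeric(nrow(rectangles))
  for (i in seq_len(nrow(rectangles))) {
    r <- rectangles[i, ]
    inner <- gel_image[r$y0:r$y1, r$x0:r$x1]
    outer_ <- gel_image[(r$y0 - f):(r$y1 + f), (r$x0 - f):(r$x1 + f)]
    bg[i] <- (sum(outer_) - sum(inner)) / (length(outer_) - length(inner))
    vol[i] <- sum(inner) - bg[i] * length(inner)
  }
  lanes <- unique(rectangles$lane)
  target <- setNames(rep(NA_real_, length(lanes)), lanes)
  loading <- target
  for (i in seq_len(nrow(rectangles))) {
    if (rectangles$band[i] == "target") target[rectangles$lane[i]] <- vol[i]
    else loading[rectangles$lane[i]] <- vol[i]
  }
  normalized <- ifelse(is.na(loading), target, target / loading)
  reference <- reference %||% lanes[1]
  if (!reference %in% lanes) stopf("reference lane '%s' not found", reference)
  fold <- normalized / normalized[reference]
  structure(list(lane_volumes = target, loading_volumes = loading,
                 local_background = setNames(bg, paste(rectangles$lane,
                                                       rectangles$band)),
                 normalized = normalized, fold_change = fold,
                 reference = reference),
            class = "densitometry_result")
}

#' @export
print.densitometry_result <- function(x, ...) {
  cat(sprintf("<densitometry_result> reference lane '%s'\n", x$reference))
  print(data.frame(lane = names(x$lane_volumes), volume = x$lane_volumes,
                   loading = x$loading_volumes, normalized = x$normalized,
                   fold_change = x$fold_change, row.names = NULL))
  invisible(x)
}
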