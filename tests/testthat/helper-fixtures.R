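# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

test_sampling <- c(0.2, 0.2, 0.4)

# A single-sphere scene: radius r um, concentration conc, centred in a field
# (constructed directly, bypassing the placement sampler).
ball_scene <- function(r = 3, conc = 2, field = c(16, 16, 12),
                       background = 0) {
  nuclei <- data.frame(id = 1L, center_x = field[1] / 2,
                       center_y = field[2] / 2, center_z = field[3] / 2,
                       cell_type = "cellA", volume = 4 / 3 * pi * r^3,
                       dna_content = NA_real_, ax_a = r, ax_b = r,
                       ax_c = r, theta = 0, conc_yfp = conc)
  structure(list(nuclei = nuclei, channels = "yfp",
                 field_size = as.numeric(field),
                 background_level = background, seed = 1L,
                 preset = "constant_concentration"),
            class = "ground_truth_scene")
}

delta_psf <- function(depth, sampling = test_sampling) {
  psf_model(optics_settings(grid_sampling = sampling), depth, mode = "one",
            delta = TRUE)
}

gauss_psf <- function(depth, sampling = test_sampling, mode = "one") {
  psf_model(optics_settings(grid_sampling = sampling), depth, mode = mode)
}

# Small constant-concentration pipeline run shared by several files.
small_constant_run <- function() {
  cached("constant_run", {
    cfg <- run_config(preset = "constant_concentration",
                      n_per_type = c(cellA = 12), seed = 11,
                      sampling = test_sampling)
    suppressWarnings(run_pipeline(cfg))
  })
}

# Small cycling population (20 nuclei) through the full pipeline.
small_cycling_run <- function() {
  cached("cycling_run", {
    cfg <- run_config(preset = "cycling_dapi", n_per_type = c(cell = 20),
                      seed = 5, sampling = test_sampling)
    suppressWarnings(run_pipeline(cfg))
  })
}

# Independent brute-force Spearman oracle: rho from first principles and,
# for tiny n, the exact permutation p by explicit enumeration (recursion
# distinct from the implementation's).
oracle_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- rx - mean(rx); my <- ry - mean(ry)
  sum(mx * my) / sqrt(sum(mx^2) * sum(my^2))
}

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

oracle_exact_p <- function(x, y) {
  r0 <- abs(oracle_rho(x, y))
  rhos <- vapply(oracle_perms(y), function(p) abs(oracle_rho(x, p)), 0)
  mean(rhos >= r0 - 1e-12)
}

# Analytic hard-edged ball stack (no optics), value inside, 0 outside.
make_mask_stack <- function(centers, r = 2.4, dims = c(80, 80, 40),
                            value = 10) {
  arr <- array(0, dims)
  for (cc in centers) {
    for (z in seq_len(dims[3])) {
      dz2 <- ((z - cc[3]) * test_sampling[3])^2
      if (dz2 > r^2) next
      rho <- sqrt(r^2 - dz2)
      xs <- (seq_len(dims[1]) - cc[1]) * test_sampling[1]
      ys <- (seq_len(dims[2]) - cc[2]) * test_sampling[2]
      arr[, , z] <- arr[, , z] + value * (outer(xs^2, ys^2, `+`) <= rho^2)
    }
  }
  image_stack(arr, test_sampling)
}

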