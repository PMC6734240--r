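#' Detector noise model
#'
#' Poisson photon noise followed by Gaussian read noise and a baseline
#' offset: a voxel with expected brightness \eqn{s} (a.u., including the
#' diffuse background) is recorded as
#' \deqn{y = Pois(ps \cdot s)/ps + N(0, \sigma_r) + o}
#' with `photon_scale` \eqn{ps} (expected photons per a.u.), read noise
#' \eqn{\sigma_r} (a.u.) and detector `offset` \eqn{o} (a.u.).
#' `photon_scale = Inf` disables shot noise.
#'
#' @param photon_scale expected photons per a.u. (> 0, may be `Inf`).
#' @param read_sigma Gaussian read-noise SD, a.u. (>= 0).
#' @param offset detector baseline, a.u.
#' @return A `noise_model` list.
#' @export
noise_model <- function(photon_scale = 40, read_sigma = 0.05, offset = 0.1) {
  stopifnot(photon_scale > 0, read_sigma >= 0)
  structure(list(photon_scale = photon_scale, read_sigma = read_sigma,
                 offset = offset), class = "noise_model")
}

# Sub-voxel coverage of one ellipsoid on the voxel grid. Voxels whose centre
# is safely inside (outside) get coverage 1 (0); voxels near the surface are
# supersampled 3x3x3. Returns the indices and coverages of touched voxels.
ellipsoid_coverage <- function(nuc, sampling, dims) {
  ax <- c(nuc$ax_a, nuc$ax_b, nuc$ax_c)
  ct <- cos(nuc$theta); st <- sin(nuc$theta)
  ext <- c(sqrt((ax[1] * ct)^2 + (ax[2] * st)^2),
           sqrt((ax[1] * st)^2 + (ax[2] * ct)^2), ax[3])
  cen <- c(nuc$center_x, nuc$center_y, nuc$center_z)
  half <- 0.5 * sqrt(sum(sampling^2))
  i0 <- pmax(1L, floor((cen - ext - half) / sampling) + 1L)
  i1 <- pmin(dims, ceiling((cen + ext + half) / sampling))
  if (any(i1 < i0)) return(NULL)
  xs <- (i0[1]:i1[1] - 0.5) * sampling[1] - cen[1]
  ys <- (i0[2]:i1[2] - 0.5) * sampling[2] - cen[2]
  zs <- (i0[3]:i1[3] - 0.5) * sampling[3] - cen[3]
  nb <- c(length(xs), length(ys), length(zs))
  X <- rep(xs, times = nb[2] * nb[3])
  Y <- rep(rep(ys, each = nb[1]), times = nb[3])
  Z <- rep(zs, each = nb[1] * nb[2])
  qr <- function(X, Y, Z) {
    u <- (X * ct + Y * st) / ax[1]
    v <- (-X * st + Y * ct) / ax[2]
    w <- Z / ax[3]
    sqrt(u * u + v * v + w * w)
  }
  r <- qr(X, Y, Z)
  delta <- 1.05 * half / min(ax)
  cov <- as.numeric(r <= 1 - delta)
  bnd <- which(r > 1 - delta & r < 1 + delta)
  if (length(bnd)) {
    off <- c(-1, 0, 1) / 3
    acc <- numeric(length(bnd))
    for (ox in off) for (oy in off) for (oz in off)
      acc <- acc + (qr(X[bnd] + ox * sampling[1], Y[bnd] + oy * sampling[2],
                       Z[bnd] + oz * sampling[3]) <= 1)
    cov[bnd] <- acc / 27
  }
  keep <- which(cov > 0)
  if (!length(keep)) return(NULL)
  kx <- (keep - 1) %% nb[1]
  ky <- ((keep - 1) %/% nb[1]) %% nb[2]
  kz <- (keep - 1) %/% (nb[1] * nb[2])
  list(index = (i0[1] + kx) + dims[1] * ((i0[2] + ky - 1) +
         dims[2] * (i0[3] + kz - 1)),
       coverage = cov[keep])
}

# Noise-free, PSF-free expected image of a scene (the oracle renderer):
# voxel value = concentration x sub-voxel coverage, per channel, plus the
# diffuse background. Every rendered voxel's expectation is reconstructible
# from the truth record alone.
#' Render the expected (noise-free, unblurred) image of a scene
#'
#' @param scene a `ground_truth_scene`.
#' @param sampling voxel size, µm.
#' @param background include the scene's diffuse background level.
#' @return An [image_stack] of expected brightness in a.u. (concentration
#'   units): summing `voxels * voxel_volume` over a nucleus gives
#'   `concentration * volume`.
#' @export
render_expected <- function(scene, sampling, background = TRUE) {
  sampling <- as.numeric(sampling)
  dims <- pmax(ceiling(scene$field_size / sampling), 1)
  conc <- scene_concentrations(scene)
  nch <- length(scene$channels)
  arr <- array(0, c(dims, nch))
  npx <- prod(dims)
  for (i in seq_len(nrow(scene$nuclei))) {
    cv <- ellipsoid_coverage(scene$nuclei[i, ], sampling, dims)
    if (is.null(cv)) next
    for (ch in seq_len(nch))
      arr[cv$index + (ch - 1) * npx] <- arr[cv$index + (ch - 1) * npx] +
        conc[i, ch] * cv$coverage
  }
  if (background) arr <- arr + scene$background_level
  image_stack(arr, sampling, scene$channels)
}

#' Render a scene into a realistic confocal stack
#'
#' Voxelizes each ellipsoid at its uniform concentration (3x3x3
#' supersampling of surface voxels), adds the diffuse background, blurs with
#' the depth-appropriate PSF brick, then applies Poisson photon noise,
#' Gaussian read noise and the detector offset. For an isolated interior
#' nucleus the expected integrated signal equals
#' `concentration x true volume` (in a.u. µm³) up to sub-percent
#' voxelization and boundary spill.
#'
#' @param scene a `ground_truth_scene`.
#' @param psf a [psf_model()] (built for this sampling and stack depth), or
#'   `NULL` to build the default one (brick mode "more").
#' @param noise a [noise_model()]; `NULL` for the default.
#' @param sampling voxel size, µm.
#' @param seed integer; rendering is bit-reproducible given
#'   (scene, psf, noise, seed).
#' @return An [image_stack] with attribute `"scene"`.
#' @export
render_stack <- function(scene, psf = NULL, noise = noise_model(),
                         sampling = c(0.2, 0.2, 0.4), seed = 1L) {
  sampling <- as.numeric(sampling)
  stopifnot(all(sampling > 0))
  expected <- render_expected(scene, sampling, background = TRUE)
  if (is.null(psf)) {
    opt <- optics_settings(grid_sampling = sampling)
    psf <- psf_model(opt, stack_depth = dim_stack(expected)[3] * sampling[3])
  }
  if (any(abs(psf$settings$grid_sampling - sampling) > 1e-9))
    stopf("PSF grid sampling does not match the requested stack sampling")
  arr <- expected$data
  for (ch in seq_len(n_channels(expected)))
    arr[, , , ch] <- apply_psf(stack_channel(expected, ch), psf)
  if (!is.null(noise)) {
    ps <- noise$photon_scale
    with_seed(seed, {
      if (is.finite(ps))
        arr[] <- rpois(length(arr), ps * pmax(arr, 0)) / ps
      if (noise$read_sigma > 0)
        arr[] <- arr + rnorm(length(arr), 0, noise$read_sigma)
      arr[] <- arr + noise$offset
    })
  }
  out <- image_stack(arr, sampling, scene$channels)
  attr(out, "scene") <- scene
  out
}
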