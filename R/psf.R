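#' Theoretical confocal point-spread functions
#'
#' The PSF is modelled as a separable 3-D Gaussian. With emission wavelength
#' \eqn{\lambda} (nm), numerical aperture NA and immersion refractive index
#' \eqn{n}, the lateral and axial standard deviations are
#' \deqn{\sigma_{xy} = k_{xy} \lambda / NA, \qquad
#'       \sigma_z = k_z \lambda n / NA^2,}
#' with \eqn{k_{xy} = 0.30} and \eqn{k_z = 0.80} (package conventions,
#' intermediate between the widefield diffraction limit and the blur of a
#' real pinhole at typical openings). Spherical-aberration growth with
#' imaging depth is a linear inflation of the axial width,
#' \eqn{\sigma_z(d) = \sigma_z (1 + \beta d)} with `depth_aberration`
#' \eqn{\beta} per µm, so deeper bricks get blurrier kernels.
#'
#' @param settings list of optical parameters; see [optics_settings()].
#' @param depth imaging depth in µm (>= 0).
#' @return A `psf_kernel`: separable kernel components `kx`, `ky`, `kz`
#'   (each non-negative, unit sum), plus the sigmas used. Use
#'   [psf_kernel_array()] for the full 3-D kernel.
#' @examples
#' k <- theoretical_psf(optics_settings(grid_sampling = c(0.2, 0.2, 0.4)), 0)
#' sum(psf_kernel_array(k))   # 1
#' @export
theoretical_psf <- function(settings, depth = 0) {
  s <- settings
  if (depth < 0) stopf("depth must be >= 0")
  lam <- s$emission_wavelength / 1000          # nm -> um
  sxy <- 0.30 * lam / s$numerical_aperture
  sz <- 0.80 * lam * s$refractive_index_immersion / s$numerical_aperture^2
  sz <- sz * (1 + s$depth_aberration * depth)
  dv <- s$grid_sampling
  if (sxy < 0.5 * min(dv[1:2]))
    stopf(paste("lateral PSF sigma (%.3f um) is under half a voxel at",
                "sampling %.3f um: use finer x/y sampling"), sxy, min(dv[1:2]))
  structure(list(kx = gaussian_kernel1d(sxy, dv[1]),
                 ky = gaussian_kernel1d(sxy, dv[2]),
                 kz = gaussian_kernel1d(sz, dv[3]),
                 sigma_xy = sxy, sigma_z = sz, depth = depth,
                 sampling = dv),
            class = "psf_kernel")
}

#' @rdname theoretical_psf
#' @param numerical_aperture objective NA (40x/1.30 oil default).
#' @param emission_wavelength nm (YFP ~527).
#' @param refractive_index_immersion immersion oil.
#' @param grid_sampling voxel size, µm.
#' @param depth_aberration axial-width inflation per µm of depth.
#' @export
optics_settings <- function(numerical_aperture = 1.30,
                            emission_wavelength = 527,
                            refractive_index_immersion = 1.515,
                            grid_sampling = c(0.112, 0.112, 0.200),
                            depth_aberration = 0.02) {
  stopifnot(numerical_aperture > 0, emission_wavelength > 0,
            refractive_index_immersion > 0, all(grid_sampling > 0),
            depth_aberration >= 0)
  list(numerical_aperture = numerical_aperture,
       emission_wavelength = emission_wavelength,
       refractive_index_immersion = refractive_index_immersion,
       grid_sampling = as.numeric(grid_sampling),
       depth_aberration = depth_aberration)
}

# Voxel-integrated 1-D Gaussian, tails trimmed where the per-tail mass drops
# below `tail_mass`, renormalized to unit sum.
gaussian_kernel1d <- function(sigma, dv, tail_mass = 1e-6) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(6 * sigma / dv))
  i <- -h:h
  k <- stats::pnorm((i + 0.5) * dv, sd = sigma) -
       stats::pnorm((i - 0.5) * dv, sd = sigma)
  cum <- cumsum(k)
  keep <- cum > tail_mass & rev(cumsum(rev(k))) > tail_mass
  if (any(keep)) k <- k[keep]
  k / sum(k)
}

#' @rdname theoretical_psf
#' @param kernel a `psf_kernel`.
#' @export
psf_kernel_array <- function(kernel) {
  a <- outer(outer(kernel$kx, kernel$ky), kernel$kz)
  dim(a) <- c(length(kernel$kx), length(kernel$ky), length(kernel$kz))
  a
}

# Identity optics: a one-voxel delta kernel (used for tests and as the
# "no blur" PSF option).
delta_kernel <- function(sampling) {
  structure(list(kx = 1, ky = 1, kz = 1, sigma_xy = 0, sigma_z = 0,
                 depth = 0, sampling = as.numeric(sampling)),
            class = "psf_kernel")
}

#' Depth bricks
#'
#' Partitions the imaging depth `[0, stack_depth]` into contiguous slabs
#' ("bricks"), each of which is deconvolved (or rendered) with the PSF
#' evaluated at its mid-depth. `mode = "more"` uses 6 bricks, `"few"` 2 and
#' `"one"` a single brick.
#'
#' @param stack_depth total depth, µm.
#' @param mode brick density.
#' @return Numeric vector of brick boundaries (length n_bricks + 1),
#'   strictly increasing from 0 to `stack_depth`.
#' @export
build_bricks <- function(stack_depth, mode = c("more", "few", "one")) {
  mode <- match.arg(mode)
  if (stack_depth <= 0) stopf("stack_depth must be > 0")
  n <- c(more = 6L, few = 2L, one = 1L)[[mode]]
  seq(0, stack_depth, length.out = n + 1L)
}

#' Depth-resolved PSF model
#'
#' Combines [build_bricks()] and [theoretical_psf()]: one normalized kernel
#' per brick, evaluated at the brick's mid-depth.
#'
#' @param settings output of [optics_settings()]; its `grid_sampling` must
#'   match the stack the model is applied to.
#' @param stack_depth stack depth in µm.
#' @param mode brick density (see [build_bricks()]).
#' @param delta if `TRUE`, every brick gets an identity (delta) kernel.
#' @return A `psf_model`: list with `brick_boundaries` (µm),
#'   `per_brick_kernels`, and the optical settings.
#' @export
psf_model <- function(settings = optics_settings(), stack_depth,
                      mode = "more", delta = FALSE) {
  bounds <- build_bricks(stack_depth, mode)
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  kernels <- lapply(mids, function(d)
    if (delta) delta_kernel(settings$grid_sampling)
    else theoretical_psf(settings, d))
  structure(list(brick_boundaries = bounds, per_brick_kernels = kernels,
                 settings = settings, mode = mode),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("<psf_model> %d brick(s) over [0, %.1f] um (mode '%s')\n",
              length(x$per_brick_kernels), max(x$brick_boundaries), x$mode))
  for (i in seq_along(x$per_brick_kernels)) {
    k <- x$per_brick_kernels[[i]]
    cat(sprintf("  brick %d: depth %5.2f um, sigma_xy %.3f um, sigma_z %.3f um\n",
                i, k$depth, k$sigma_xy, k$sigma_z))
  }
  invisible(x)
}
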