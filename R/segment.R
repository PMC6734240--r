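#' Estimate the background / non-specific fluorescence level
#'
#' The iso-surface threshold is anchored at the background signal: the mode
#' of the voxel-intensity distribution (kernel density argmax) plus
#' `k` times the scaled median absolute deviation. Both components are
#' reported. For stacks above `max_sample` voxels a deterministic stride
#' subsample is used.
#'
#' @param stack an [image_stack] (or bare 3-D array).
#' @param channel channel to estimate from.
#' @param k MAD multiplier for the threshold (default 3).
#' @param max_sample voxel subsample cap for the density estimate.
#' @return A `background_estimate`: list with `mode`, `mad` (scaled,
#'   consistent with a Gaussian SD) and `threshold = mode + k * mad`.
#' @export
estimate_background <- function(stack, channel = 1L, k = 3,
                                max_sample = 2e6) {
  v <- if (inherits(stack, "image_stack")) stack_channel(stack, channel)
       else stack
  v <- as.numeric(v)
  if (!length(v)) stopf("empty stack")
  if (length(v) > max_sample)
    v <- v[seq(1L, length(v), by = ceiling(length(v) / max_sample))]
  if (max(v) == min(v))
    stopf("constant image: background level is undefined")
  d <- density(v, n = 2048)
  md <- d$x[which.max(d$y)]
  s <- mad(v, center = md)
  if (s == 0) s <- mad(v)
  structure(list(mode = md, mad = s, k = k, threshold = md + k * s),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("<background_estimate> mode %.4g, MAD %.4g, threshold (mode + %g MAD) %.4g a.u.\n",
              x$mode, x$mad, x$k, x$threshold))
  invisible(x)
}

as_threshold <- function(x) {
  if (inherits(x, "background_estimate")) x$threshold else as.numeric(x)
}

#' Iso-surface segmentation of nuclei
#'
#' Binarizes the stack at the background threshold, fills internal holes
#' slice by slice, labels connected components (26-connectivity by default)
#' and applies the quality filters: components below `min_volume` are
#' dropped as `too_small`, components touching any stack face as
#' `truncated` (their volume integral would be incomplete), and components
#' larger than `merged_multiple` times the robust median candidate volume
#' as `merged` (under-segmented clumps). Kept labels are renumbered
#' contiguously from 1.
#'
#' @param stack an [image_stack].
#' @param threshold iso-surface level in a.u., or a `background_estimate`;
#'   `NULL` estimates it from the stack via [estimate_background()].
#' @param min_volume µm³; smaller components are rejected.
#' @param channel channel to segment on.
#' @param merged_multiple multiple of the robust median volume above which
#'   a component counts as merged.
#' @param connectivity 26 (default) or 6.
#' @param fill_holes fill internal 2-D holes per z-slice.
#' @return A `segmentation_result`: list with `label_map` (integer array),
#'   `threshold_used`, `n_raw`, `n_kept`, `rejected` (data frame of label
#'   and reason), `volumes` (kept, µm³) and `sampling`.
#' @export
segment_nuclei <- function(stack, threshold = NULL, min_volume = 30,
                           channel = 1L, merged_multiple = 2.5,
                           connectivity = 26L, fill_holes = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  arr <- stack_channel(stack, channel)
  if (is.null(threshold)) threshold <- estimate_background(stack, channel)
  thr <- as_threshold(threshold)
  if (thr <= min(arr))
    stopf("threshold %.4g is at or below the stack minimum", thr)
  dims <- dim(arr)
  mask <- array(as.integer(arr > thr), dims)
  if (fill_holes) mask <- fill_holes_slices_cpp(mask, dims)
  lab <- label3d_cpp(mask, dims, as.integer(connectivity))
  n_raw <- max(lab)
  if (n_raw == 0L) {
    warnf("no components found above threshold %.4g", thr)
    return(structure(list(label_map = lab, threshold_used = thr,
                          n_raw = 0L, n_kept = 0L,
                          rejected = data.frame(label = integer(),
                                                reason = character()),
                          volumes = numeric(), sampling = stack$sampling,
                          channel = channel),
                     class = "segmentation_result"))
  }
  vox <- prod(stack$sampling)
  counts <- tabulate(lab, nbins = n_raw)
  vols <- counts * vox
  faces <- unique(c(lab[1, , ], lab[dims[1], , ], lab[, 1, ],
                    lab[, dims[2], ], lab[, , 1], lab[, , dims[3]]))
  truncated <- seq_len(n_raw) %in% setdiff(faces, 0L)
  too_small <- vols < min_volume & !truncated
  cand <- !too_small & !truncated
  merged <- rep(FALSE, n_raw)
  if (any(cand)) {
    med <- median(vols[cand])
    merged <- cand & vols > merged_multiple * med
  }
  keep <- cand & !merged
  reason <- rep(NA_character_, n_raw)
  reason[truncated] <- "truncated"
  reason[too_small] <- "too_small"
  reason[merged] <- "merged"
  lut <- integer(n_raw + 1L)
  lut[which(keep) + 1L] <- seq_len(sum(keep))
  lab[] <- lut[lab + 1L]
  structure(list(label_map = lab, threshold_used = thr,
                 n_raw = n_raw, n_kept = sum(keep),
                 rejected = data.frame(label = which(!keep),
                                       reason = reason[!keep]),
                 volumes = vols[keep], sampling = stack$sampling,
                 channel = channel),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> threshold %.4g a.u.: %d raw -> %d kept\n",
              x$threshold_used, x$n_raw, x$n_kept))
  if (nrow(x$rejected)) print(table(x$rejected$reason))
  invisible(x)
}
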