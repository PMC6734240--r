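#' Pipeline run configuration
#'
#' Bundles every knob of the simulate → deconvolve → segment → measure →
#' stats pipeline into one serializable object. Defaults follow the
#' acquisition regime the pipeline emulates (40x/1.30 oil objective,
#' 0.112 µm x/y and 0.200 µm z sampling); the coarser `test geometry`
#' (0.2/0.2/0.4 µm) used throughout the package's own simulations is set
#' via `sampling`.
#'
#' @param preset scene preset (see [sample_scene()]).
#' @param n_per_type named nucleus counts per cell type.
#' @param seed master seed; every stage seed derives from it.
#' @param sampling voxel size, µm.
#' @param scene_params overrides for the scene preset.
#' @param optics [optics_settings()] parameters (grid sampling is forced to
#'   `sampling`).
#' @param brick_mode depth-brick density for the PSF model.
#' @param noise a [noise_model()].
#' @param deconvolution a [deconv_settings()] (its background estimate is
#'   filled in at run time from the raw stack).
#' @param segmentation list: `threshold` ("auto" or a number),
#'   `min_volume` (µm³), `merged_multiple`, `connectivity`, `channel`.
#' @param stats list: `n_boot`, `bandwidth` (ploidy KDE, NULL = Silverman),
#'   `prominence_frac`.
#' @param fast_volume also compute the ellipsoid fast-volume table.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = "constant_concentration",
                       n_per_type = c(cellA = 16), seed = 1L,
                       sampling = c(0.112, 0.112, 0.200),
                       scene_params = list(),
                       optics = optics_settings(grid_sampling = sampling),
                       brick_mode = "more",
                       noise = noise_model(),
                       deconvolution = deconv_settings(),
                       segmentation = list(),
                       stats = list(),
                       fast_volume = FALSE) {
  sampling <- as.numeric(sampling)
  stopifnot(all(sampling > 0))
  optics$grid_sampling <- sampling
  seg <- utils::modifyList(list(threshold = "auto", threshold_k = 3, min_volume = 30,
                                merged_multiple = 2.5, connectivity = 26L,
                                channel = 1L), segmentation)
  st <- utils::modifyList(list(n_boot = 2000, bandwidth = NULL,
                               prominence_frac = 0.05), stats)
  structure(list(preset = preset, n_per_type = n_per_type,
                 seed = as.integer(seed), sampling = sampling,
                 scene_params = scene_params, optics = optics,
                 brick_mode = brick_mode, noise = noise,
                 deconvolution = deconvolution, segmentation = seg,
                 stats = st, fast_volume = fast_volume),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  config$n_per_type <- as.list(config$n_per_type)   # keep names for n = 1
  jsonlite::write_json(strip_classes(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  drop_null <- function(x) x[!vapply(x, is.null, TRUE)]
  run_config(preset = o$preset, n_per_type = unlist(o$n_per_type),
             seed = o$seed, sampling = o$sampling,
             scene_params = o$scene_params %||% list(),
             optics = do.call(optics_settings,
                              o$optics[names(o$optics) != "grid_sampling"]),
             brick_mode = o$brick_mode,
             noise = do.call(noise_model, o$noise),
             deconvolution = do.call(deconv_settings, o$deconvolution),
             segmentation = drop_null(as.list(o$segmentation)),
             stats = drop_null(as.list(o$stats)),
             fast_volume = isTRUE(o$fast_volume))
}

config_hash <- function(config) {
  content_hash(jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

# Match measured nuclei to truth nuclei by nearest centroid.
match_to_truth <- function(scene, measurements, max_dist = 3) {
  m <- measurements[!duplicated(measurements$label), ]
  tx <- scene$nuclei$center_x; ty <- scene$nuclei$center_y
  tz <- scene$nuclei$center_z
  conc <- scene_concentrations(scene)
  out <- lapply(seq_len(nrow(m)), function(i) {
    d2 <- (tx - m$centroid_x[i])^2 + (ty - m$centroid_y[i])^2 +
          (tz - m$centroid_z[i])^2
    j <- which.min(d2)
    data.frame(label = m$label[i], truth_id = scene$nuclei$id[j],
               cell_type = scene$nuclei$cell_type[j],
               distance = sqrt(d2[j]),
               matched = sqrt(d2[j]) <= max_dist,
               true_volume = scene$nuclei$volume[j],
               measured_volume = m$volume[i],
               true_total = conc[j, 1] * scene$nuclei$volume[j],
               measured_total = m$total_signal[i],
               true_dna = scene$nuclei$dna_content[j])
  })
  do.call(rbind, out)
}

run_stage <- function(prov, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  warns <- character()
  res <- withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  prov$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  if (length(warns)) prov$warnings[[name]] <- warns
  list(prov = prov, value = res)
}

#' Run the full quantification pipeline
#'
#' Executes simulate (optional) → deconvolve → segment → measure → stats in
#' order. In `"simulate_and_analyze"` mode a scene is sampled and rendered
#' from the configuration; in `"analyze_only"` mode a `stack` (and
#' optionally its truth `scene`, for comparison tables) is supplied. If
#' `out_dir` is given, the bundle is written: `measurements.csv`,
#' `stats.json`, `labels.tif`, `scene.json`, `comparison.csv` and
#' `provenance.json`.
#'
#' @param config a [run_config()].
#' @param mode `"simulate_and_analyze"` or `"analyze_only"`.
#' @param out_dir optional output directory.
#' @param stack an [image_stack] for `"analyze_only"`.
#' @param scene optional truth scene for `"analyze_only"`.
#' @return A list bundle: `scene`, `stack`, `deconvolved`, `background`,
#'   `segmentation`, `measurements` (plus `fast_measurements` if
#'   configured), `comparison`, `stats`, `provenance`.
#' @export
run_pipeline <- function(config, mode = c("simulate_and_analyze",
                                          "analyze_only"),
                         out_dir = NULL, stack = NULL, scene = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "run_config"))
  prov <- list(config_hash = config_hash(config),
               package_version = as.character(packageVersion("nucquant")),
               seed = config$seed, mode = mode,
               timings = list(), warnings = list())
  seeds <- derive_seeds(config$seed, 3)

  if (mode == "simulate_and_analyze") {
    s <- run_stage(prov, "simulate", {
      scene <- sample_scene(config$preset, config$n_per_type,
                            seed = config$seed,
                            params = config$scene_params)
      depth <- ceiling(scene$field_size[3] / config$sampling[3]) *
        config$sampling[3]
      psf <- psf_model(config$optics, stack_depth = depth,
                       mode = config$brick_mode)
      render_stack(scene, psf, config$noise, config$sampling,
                   seed = seeds[1])
    })
    prov <- s$prov; stack <- s$value
    scene <- attr(stack, "scene")
  } else if (is.null(stack)) {
    stopf("analyze_only mode needs a `stack`")
  }

  segch <- config$segmentation$channel
  s <- run_stage(prov, "background", estimate_background(stack, segch))
  prov <- s$prov; bg <- s$value

  s <- run_stage(prov, "deconvolve", {
    depth <- dim_stack(stack)[3] * stack$sampling[3]
    psf <- psf_model(config$optics, stack_depth = depth,
                     mode = config$brick_mode)
    dset <- config$deconvolution
    dset$background_estimate <- bg$mode
    deconvolve_mle(stack, psf, dset)
  })
  prov <- s$prov; decon <- s$value

  s <- run_stage(prov, "segment", {
    thr <- config$segmentation$threshold
    # the restored stack is background-free, so the iso-surface level
    # "corresponding to the background signal" reduces to k x the raw
    # background noise scale (MAD)
    if (identical(thr, "auto")) thr <- config$segmentation$threshold_k * bg$mad
    segment_nuclei(decon, threshold = thr,
                   min_volume = config$segmentation$min_volume,
                   channel = segch,
                   merged_multiple = config$segmentation$merged_multiple,
                   connectivity = config$segmentation$connectivity)
  })
  prov <- s$prov; seg <- s$value

  s <- run_stage(prov, "measure", measure_nuclei(decon, seg))
  prov <- s$prov; meas <- s$value
  fast <- NULL
  if (isTRUE(config$fast_volume)) {
    s <- run_stage(prov, "measure_fast", measure_ellipsoid_fast(decon, seg))
    prov <- s$prov; fast <- s$value
  }

  comparison <- if (!is.null(scene) && nrow(meas))
    match_to_truth(scene, get_channel(meas, meas$channel[1])) else NULL

  s <- run_stage(prov, "stats", pipeline_stats(config, scene, meas, seeds[2]))
  prov <- s$prov; stats <- s$value

  bundle <- list(scene = scene, stack = stack, deconvolved = decon,
                 background = bg, segmentation = seg, measurements = meas,
                 fast_measurements = fast, comparison = comparison,
                 stats = stats, provenance = prov)
  if (!is.null(out_dir)) write_bundle(bundle, config, out_dir)
  bundle
}

# Statistics stage: which readouts run depends on the channels present.
pipeline_stats <- function(config, scene, meas, seed) {
  out <- list()
  if (!nrow(meas)) return(out)
  nb <- config$stats$n_boot
  channels <- unique(meas$channel)
  for (ch in channels) {
    m <- get_channel(meas, ch)
    if (nrow(m) >= 5 && length(unique(m$volume)) > 1)
      out[[paste0("concentration_fit_", ch)]] <-
        fit_constant_concentration(m, n_boot = nb, seed = seed)
  }
  if ("dna" %in% channels) {
    m <- get_channel(meas, "dna")
    if (nrow(m) >= 3)
      out$ploidy <- ploidy_peaks(m$total_signal,
                                 bandwidth = config$stats$bandwidth,
                                 prominence_frac = config$stats$prominence_frac,
                                 seed = seed)
  }
  if (length(channels) >= 2) {
    a <- get_channel(meas, channels[1]); b <- get_channel(meas, channels[2])
    out$correlation <- spearman_correlation(a$total_signal, b$total_signal,
                                            channel_pair = channels[1:2],
                                            seed = seed)
  }
  if (!is.null(scene) && length(unique(scene$nuclei$cell_type)) == 2 &&
      nrow(meas)) {
    cmp <- match_to_truth(scene, get_channel(meas, channels[1]))
    types <- sort(unique(scene$nuclei$cell_type))
    m1 <- get_channel(meas, channels[1])
    ga <- m1[m1$label %in% cmp$label[cmp$matched & cmp$cell_type == types[1]], ]
    gb <- m1[m1$label %in% cmp$label[cmp$matched & cmp$cell_type == types[2]], ]
    if (nrow(ga) >= 3 && nrow(gb) >= 3)
      out$type_ratio <- c(list(types = types),
                          unclass(concentration_ratio(ga, gb, n_boot = nb,
                                                      seed = seed)))
  }
  out
}

stats_to_json <- function(stats) {
  strip <- function(x) {
    if (inherits(x, "ploidy_result")) x$density <- NULL
    if (inherits(x, "concentration_fit")) x[c("totals", "volumes")] <- NULL
    unclass(x)
  }
  lapply(stats, strip)
}

write_bundle <- function(bundle, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_measurements(bundle$measurements, file.path(out_dir, "measurements.csv"))
  if (!is.null(bundle$fast_measurements))
    write_measurements(bundle$fast_measurements,
                       file.path(out_dir, "measurements_fast.csv"))
  jsonlite::write_json(strip_classes(stats_to_json(bundle$stats)),
                       file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  lab <- image_stack(array(as.numeric(bundle$segmentation$label_map),
                           dim(bundle$segmentation$label_map)),
                     bundle$stack$sampling, "labels")
  write_stack(lab, file.path(out_dir, "labels.tif"), bits = 16L)
  if (!is.null(bundle$scene))
    write_scene(bundle$scene, file.path(out_dir, "scene.json"))
  if (!is.null(bundle$comparison))
    write.csv(bundle$comparison, file.path(out_dir, "comparison.csv"),
              row.names = FALSE)
  write_config(config, file.path(out_dir, "config.json"))
  jsonlite::write_json(bundle$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
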