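#' Ground-truth scene presets
#'
#' A scene is the simulator's truth record: nuclei as z-axis-tilted
#' ellipsoids, each with a centre and semi-axes (µm), a cell-type label, a
#' per-channel fluorophore concentration (a.u. per µm³) and, where relevant,
#' a DNA content (multiple of the G1 amount). Registered presets emulate the
#' study designs the statistics stage is aimed at:
#'
#' * `"cortex"` — two populations: neuron-like nuclei (mean volume 520 µm³,
#'   lognormal scatter CV 15%) at concentration 5.0 a.u./µm³ and glia-like
#'   nuclei (mean 150 µm³) at 1.0 a.u./µm³: a fixed fivefold concentration
#'   contrast. Channel: `yfp`.
#' * `"constant_concentration"` — one population sharing a single
#'   concentration (default 3.0 a.u./µm³) with volumes spread over at least
#'   a twofold range (log-spaced 250–520 µm³, shuffled), so total signal is
#'   proportional to volume by construction.
#' * `"cycling_dapi"` — a proliferating population with DNA content 1.0 (G1
#'   fraction), 2.0 (G2) and uniform in (1, 2) (S), default fractions
#'   0.55/0.15/0.30. Nuclear volume scales with DNA content; the integrated
#'   DNA-channel total is content times a multiplicative staining factor
#'   (CV 5%), so totals form peaks at ratio 2. Channel: `dna`.
#' * `"correlated_channels"` — two channels per nucleus (`mrna`, `tf`).
#'   With `coupling = "linear"` (transcription-factor-like) the channel-2
#'   concentration is `alpha` times channel 1 plus Gaussian noise; with
#'   `coupling = "independent"` (RNA-polymerase-like) the two are drawn
#'   independently.
#'
#' Nuclei are placed by rejection sampling with a minimum surface gap
#' (default 1 µm) and a margin from the field faces, so no truth nucleus is
#' truncated. If `field_size` is omitted, the lateral field is sized so the
#' summed bounding volumes fill at most 25% of the field (z fixed at 30 µm,
#' matching the tissue-stack depth regime) — a tissue-like nuclear density.
#'
#' @param preset one of `"cortex"`, `"constant_concentration"`,
#'   `"cycling_dapi"`, `"correlated_channels"`.
#' @param n_per_type named integer vector/list: nuclei per cell type. The
#'   single-population presets accept one entry with any type name.
#' @param seed integer; all scene randomness flows from it.
#' @param field_size optional `(Lx, Ly, Lz)` in µm.
#' @param params named list overriding preset parameters (e.g.
#'   `fractions`, `stain_cv`, `concentration`, `alpha`, `coupling`,
#'   `background_level`).
#' @return A `ground_truth_scene`: list with `nuclei` (data frame: id,
#'   cell_type, centre, semi-axes, orientation `theta`, `dna_content`,
#'   `volume`, and one `conc_<channel>` column per channel), `channels`,
#'   `field_size`, `background_level`, `seed`, `preset`.
#' @examples
#' sc <- sample_scene("constant_concentration", c(cellA = 10), seed = 1)
#' nrow(sc$nuclei)
#' @export
sample_scene <- function(preset, n_per_type, seed, field_size = NULL,
                         params = list()) {
  presets <- c("cortex", "constant_concentration", "cycling_dapi",
               "correlated_channels")
  if (!preset %in% presets)
    stopf("unknown preset '%s' (registered: %s)", preset,
          paste(presets, collapse = ", "))
  n_per_type <- unlist(n_per_type)
  if (is.null(names(n_per_type)) || any(n_per_type < 1))
    stopf("n_per_type must be a named vector with counts >= 1")
  p <- utils::modifyList(scene_defaults(preset), params)
  with_seed(seed, {
    truth <- switch(preset,
      cortex = sample_cortex(n_per_type, p),
      constant_concentration = sample_constant(n_per_type, p),
      cycling_dapi = sample_cycling(n_per_type, p),
      correlated_channels = sample_correlated(n_per_type, p))
    nuc <- place_nuclei(truth$nuclei, field_size, p)
  })
  structure(list(nuclei = nuc$nuclei, channels = truth$channels,
                 field_size = nuc$field_size,
                 background_level = p$background_level,
                 seed = as.integer(seed), preset = preset),
            class = "ground_truth_scene")
}

scene_defaults <- function(preset) {
  base <- list(background_level = 0.05, gap = 1.0, margin = 1.5,
               max_attempts = 5000L, packing = 0.25, depth = 30)
  extra <- switch(preset,
    cortex = list(
      types = list(
        neuron = list(mean_volume = 520, cv_volume = 0.15, concentration = 5.0),
        glia   = list(mean_volume = 150, cv_volume = 0.15, concentration = 1.0))),
    constant_concentration = list(concentration = 3.0,
                                  volume_range = c(250, 520)),
    cycling_dapi = list(fractions = c(g1 = 0.55, s = 0.15, g2 = 0.30),
                        base_volume = 200, cv_volume = 0.10,
                        stain_cv = 0.05, concentration = 4.0),
    correlated_channels = list(mean_volume = 250, cv_volume = 0.15,
                               mean_conc = 3.0, cv_conc = 0.35,
                               alpha = 0.8, eps_sd = 0.25,
                               coupling = "linear"))
  c(base, extra)
}

lognormal_around <- function(n, mean, cv) {
  sdl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdl^2 / 2, sdlog = sdl)
}

# Semi-axes (a >= b >= c) for given volumes: mildly flattened, z-flattest.
draw_axes <- function(vols) {
  n <- length(vols)
  kb <- runif(n, 0.85, 1.0)
  kc <- runif(n, 0.60, 0.90)
  a <- (3 * vols / (4 * pi * kb * kc))^(1 / 3)
  data.frame(ax_a = a, ax_b = a * kb, ax_c = a * kc,
             theta = runif(n, 0, pi))
}

new_truth <- function(cell_type, vols, conc, channels, dna = NA_real_) {
  ax <- draw_axes(vols)
  conc <- as.matrix(conc)
  colnames(conc) <- paste0("conc_", channels)
  cbind(data.frame(cell_type = cell_type, volume = vols,
                   dna_content = dna), ax, as.data.frame(conc))
}

sample_cortex <- function(n_per_type, p) {
  bad <- setdiff(names(n_per_type), names(p$types))
  if (length(bad)) stopf("cortex preset knows no cell type '%s'", bad[1])
  rows <- lapply(names(n_per_type), function(ty) {
    tp <- p$types[[ty]]
    vols <- lognormal_around(n_per_type[[ty]], tp$mean_volume, tp$cv_volume)
    new_truth(ty, vols, rep(tp$concentration, length(vols)), "yfp")
  })
  list(nuclei = do.call(rbind, rows), channels = "yfp")
}

sample_constant <- function(n_per_type, p) {
  ty <- names(n_per_type)[1]
  n <- n_per_type[[1]]
  vols <- if (n == 1) mean(p$volume_range) else
    sample(exp(seq(log(p$volume_range[1]), log(p$volume_range[2]),
                   length.out = n)))
  list(nuclei = new_truth(ty, vols, rep(p$concentration, n), "yfp"),
       channels = "yfp")
}

sample_cycling <- function(n_per_type, p) {
  ty <- names(n_per_type)[1]
  n <- n_per_type[[1]]
  fr <- p$fractions / sum(p$fractions)
  phase <- sample(c("g1", "s", "g2"), n, replace = TRUE, prob = fr)
  content <- ifelse(phase == "g1", 1,
                    ifelse(phase == "g2", 2, runif(n, 1, 2)))
  v0 <- lognormal_around(n, p$base_volume, p$cv_volume)
  stain <- 1 + rnorm(n, 0, p$stain_cv)
  stain <- pmax(stain, 0.5)
  vols <- v0 * content
  # total DNA signal tracks content (x stain), not nuclear volume: bigger
  # nuclei of equal content are dimmer, as for a stoichiometric DNA stain
  conc <- p$concentration * p$base_volume * content * stain / vols
  list(nuclei = new_truth(ty, vols, conc, "dna", dna = content),
       channels = "dna")
}

sample_correlated <- function(n_per_type, p) {
  ty <- names(n_per_type)[1]
  n <- n_per_type[[1]]
  vols <- lognormal_around(n, p$mean_volume, p$cv_volume)
  c1 <- lognormal_around(n, p$mean_conc, p$cv_conc)
  c2 <- if (identical(p$coupling, "independent"))
    lognormal_around(n, p$mean_conc * p$alpha, p$cv_conc)
  else pmax(p$alpha * c1 + rnorm(n, 0, p$eps_sd), 0.05)
  list(nuclei = new_truth(ty, vols, cbind(c1, c2), c("mrna", "tf")),
       channels = c("mrna", "tf"))
}

# Rejection-sample non-overlapping centres inside the field. Nuclei are
# placed largest first; a placement failure after `max_attempts` tries per
# nucleus is an error (the field is too small for the request). Auto-sized
# fields are grown by 25% and retried if packing jams, so only explicit
# `field_size` requests can fail.
place_nuclei <- function(nuc, field_size, p) {
  if (is.null(field_size)) {
    rb <- pmax(nuc$ax_a, nuc$ax_b, nuc$ax_c)
    need <- sum(4 / 3 * pi * (rb + p$gap / 2)^3) / (p$packing * p$depth)
    L <- max(40, sqrt(need), 2 * (max(rb) + p$margin) + 1)
    for (grow in c(1, 1.25, 1.25^2, 1.25^3)) {
      res <- tryCatch(place_nuclei(nuc, c(L * grow, L * grow, p$depth), p),
                      error = function(e) NULL)
      if (!is.null(res)) return(res)
    }
    stopf("could not place %d nuclei even after growing the field to %.0f um",
          nrow(nuc), L * 1.25^3)
  }
  rb <- pmax(nuc$ax_a, nuc$ax_b, nuc$ax_c)
  field_size <- as.numeric(field_size)
  ord <- order(rb, decreasing = TRUE)
  cx <- cy <- cz <- numeric(nrow(nuc))
  for (k in seq_along(ord)) {
    i <- ord[k]
    lo <- rb[i] + p$margin
    hi <- field_size - rb[i] - p$margin
    if (any(hi <= lo))
      stopf("field %.0f x %.0f x %.0f um too small for a nucleus of radius %.1f um",
            field_size[1], field_size[2], field_size[3], rb[i])
    placed <- ord[seq_len(k - 1)]
    ok <- FALSE
    for (att in seq_len(p$max_attempts)) {
      pos <- c(runif(1, lo, hi[1]), runif(1, lo, hi[2]), runif(1, lo, hi[3]))
      if (!length(placed) ||
          all((cx[placed] - pos[1])^2 + (cy[placed] - pos[2])^2 +
              (cz[placed] - pos[3])^2 >
              (rb[placed] + rb[i] + p$gap)^2)) {
        cx[i] <- pos[1]; cy[i] <- pos[2]; cz[i] <- pos[3]
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stopf("could not place nucleus %d without overlap after %d attempts; enlarge the field",
            i, p$max_attempts)
  }
  nuc <- cbind(data.frame(id = seq_len(nrow(nuc)),
                          center_x = cx, center_y = cy, center_z = cz),
               nuc)
  rownames(nuc) <- NULL
  list(nuclei = nuc, field_size = field_size)
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf("<ground_truth_scene> preset '%s', %d nuclei, seed %d\n",
              x$preset, nrow(x$nuclei), x$seed))
  cat(sprintf("  field %.1f x %.1f x %.1f um, background %.3g a.u./um^3, channels: %s\n",
              x$field_size[1], x$field_size[2], x$field_size[3],
              x$background_level, paste(x$channels, collapse = ", ")))
  print(table(x$nuclei$cell_type))
  invisible(x)
}

#' Scene (de)serialization
#'
#' Scenes round-trip through JSON: one object per nucleus, all lengths in
#' µm, the seed recorded for reproducibility.
#'
#' @param scene a `ground_truth_scene`.
#' @param path JSON file path.
#' @export
write_scene <- function(scene, path) {
  jsonlite::write_json(unclass(scene), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  o$nuclei <- as.data.frame(o$nuclei)
  o$nuclei$dna_content <- as.numeric(o$nuclei$dna_content)
  o$field_size <- as.numeric(o$field_size)
  o$seed <- as.integer(o$seed)
  structure(o, class = "ground_truth_scene")
}

scene_concentrations <- function(scene) {
  as.matrix(scene$nuclei[, paste0("conc_", scene$channels), drop = FALSE])
}
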