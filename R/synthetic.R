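#' Default retinal band specification
#'
#' Reflectivity bands drawn by the synthetic renderer, as depth-pixel offset
#' ranges relative to the RPE anchor (negative = anterior). The RPE sits at
#' the center of a 39-px hyperreflective outer complex: the photoreceptor
#' EZ/interdigitation shoulder above it and the Bruch's
#' membrane/choriocapillaris shoulder below it are drawn at equal
#' reflectivity, so the 40-px maximum mean intensity window used by
#' [locate_rpe()] is centered on the RPE in every column type. The RPE band
#' is strictly the most reflective layer.
#'
#' @return A data frame with columns `band`, `lo`, `hi`, `reflectivity`.
#' @export
default_layer_spec <- function() {
  data.frame(
    band = c("vitreous", "inner_retina", "onl", "ez_complex", "rpe",
             "choriocapillaris", "choroid"),
    lo = c(-Inf, -119, -59, -19, -4, 5, 20),
    hi = c(-120, -60, -20, -5, 4, 19, Inf),
    reflectivity = c(0.02, 0.45, 0.12, 0.55, 0.95, 0.55, 0.30))
}

#' Synthetic CSCR scene configuration
#'
#' Describes one synthetic eye: scan geometry, the resting depth of the RPE,
#' the retinal band reflectivities, dome-shaped PED and RD lesions as 2-D
#' Gaussian height bumps on the en face grid, the labeling threshold, speckle
#' noise, and an axial tilt.
#'
#' @param n_bscans,n_ascans,depth Scan geometry (defaults: the 256 x 512 x 992
#'   macular cube).
#' @param baseline_rpe_depth Depth index of the RPE (and Bruch's membrane)
#'   where no PED elevates it (default 550).
#' @param layer_spec Band table as from [default_layer_spec()]. The RPE band
#'   must be strictly the most reflective.
#' @param ped_bumps,rd_bumps Lists of lesions, each
#'   `c(center_b, center_a, sigma_b, sigma_a, height)`: a Gaussian bump on the
#'   en face grid with peak `height` in depth pixels.
#' @param lesion_threshold Minimum lesion height (depth px) for a column to be
#'   labeled with the signature (default 2); smaller elevations are
#'   sub-resolution and labeled NEITHER, mimicking a conservative human
#'   grader at lesion margins.
#' @param speckle_shape Shape of the mean-1 multiplicative gamma speckle
#'   (default 4); `0` disables noise.
#' @param tilt Axial shift in depth px per lateral pixel,
#'   `c(per_ascan, per_bscan)`, applied about the grid center.
#' @param fluid_reflectivity Reflectivity of serous fluid (default 0.05).
#' @param bm_reflectivity Reflectivity of the bared Bruch's membrane line
#'   under a PED (default 0.28, about 0.3 x RPE).
#' @param seed Integer seed controlling speckle rendering.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_bscans = 256, n_ascans = 512, depth = 992,
                         baseline_rpe_depth = 550,
                         layer_spec = default_layer_spec(),
                         ped_bumps = list(), rd_bumps = list(),
                         lesion_threshold = 2,
                         speckle_shape = 4,
                         tilt = c(0, 0),
                         fluid_reflectivity = 0.05,
                         bm_reflectivity = 0.28,
                         seed = 1L) {
  if (!is_count(n_bscans) || !is_count(n_ascans) || !is_count(depth))
    abort_validation("geometry must be positive integers")
  rpe_refl <- layer_spec$reflectivity[layer_spec$band == "rpe"]
  if (length(rpe_refl) != 1 || any(layer_spec$reflectivity[layer_spec$band != "rpe"] >= rpe_refl))
    abort_validation("the RPE band must be strictly the most reflective layer")
  if (lesion_threshold < 0) abort_validation("lesion_threshold must be >= 0")
  if (speckle_shape < 0) abort_validation("speckle_shape must be >= 0")
  if (length(tilt) == 1) tilt <- c(tilt, 0)
  cfg <- structure(
    list(n_bscans = as.integer(n_bscans), n_ascans = as.integer(n_ascans),
         depth = as.integer(depth),
         baseline_rpe_depth = as.integer(baseline_rpe_depth),
         layer_spec = layer_spec,
         ped_bumps = ped_bumps, rd_bumps = rd_bumps,
         lesion_threshold = lesion_threshold,
         speckle_shape = speckle_shape,
         tilt = as.numeric(tilt),
         fluid_reflectivity = fluid_reflectivity,
         bm_reflectivity = bm_reflectivity,
         seed = as.integer(seed)),
    class = "scene_config")
  check_scene_bounds(cfg)
  cfg
}

# anterior retina extent (inner retina start) and posterior margin must fit
check_scene_bounds <- function(cfg) {
  max_ped <- max(c(0, vapply(cfg$ped_bumps, function(b) b[5], numeric(1))))
  max_rd <- max(c(0, vapply(cfg$rd_bumps, function(b) b[5], numeric(1))))
  max_tilt <- abs(cfg$tilt[1]) * cfg$n_ascans / 2 + abs(cfg$tilt[2]) * cfg$n_bscans / 2
  top <- cfg$baseline_rpe_depth - max_tilt - max_ped - max_rd - 119
  bottom <- cfg$baseline_rpe_depth + max_tilt + 23
  if (top < 1 || bottom > cfg$depth)
    abort_validation(
      "retinal profile exceeds depth bounds: need depth indices [%g, %g] inside [1, %d]",
      top, bottom, cfg$depth)
  for (b in c(cfg$ped_bumps, cfg$rd_bumps)) {
    if (length(b) < 5) abort_validation("each bump needs (center_b, center_a, sigma_b, sigma_a, height)")
    if (b[5] < 0) abort_validation("bump heights must be >= 0")
    if (b[1] < 1 || b[1] > cfg$n_bscans || b[2] < 1 || b[2] > cfg$n_ascans)
      abort_validation("bump center (%g, %g) lies outside the en face grid", b[1], b[2])
  }
  invisible(cfg)
}

sum_bumps <- function(bumps, n_b, n_a) {
  h <- matrix(0, n_b, n_a)
  bi <- seq_len(n_b); ai <- seq_len(n_a)
  for (bump in bumps) {
    gb <- exp(-(bi - bump[1])^2 / (2 * bump[3]^2))
    ga <- exp(-(ai - bump[2])^2 / (2 * bump[4]^2))
    h <- h + bump[5] * outer(gb, ga)
  }
  h
}

tilt_field <- function(cfg) {
  bi <- seq_len(cfg$n_bscans) - (cfg$n_bscans + 1) / 2
  ai <- seq_len(cfg$n_ascans) - (cfg$n_ascans + 1) / 2
  round(outer(bi * cfg$tilt[2], ai * cfg$tilt[1], "+"))
}

#' Build the ground truth for a synthetic scene
#'
#' Evaluates the lesion height fields (sums of the configured Gaussian bumps,
#' rounded to whole depth pixels), the true RPE depth per A-scan (baseline
#' minus PED elevation, plus tilt), and the en face label map. Labels follow
#' the precedence rule: `PED` where `ped_height > lesion_threshold`, else
#' `RD` where `rd_height > lesion_threshold`, else `NEITHER`. Deterministic:
#' no randomness is consumed.
#'
#' @param config A [scene_config()].
#' @return Object of class `scene_ground_truth` with fields `ped_height`,
#'   `rd_height` (integer depth px), `rpe_depth_true`, `label_map`.
#' @export
make_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  check_scene_bounds(config)
  ped <- round(sum_bumps(config$ped_bumps, config$n_bscans, config$n_ascans))
  rd <- round(sum_bumps(config$rd_bumps, config$n_bscans, config$n_ascans))
  # heights at or below the threshold are sub-resolution: they neither render
  # nor count as lesion, keeping the label rule and the rendered scene in
  # exact agreement at lesion margins
  ped[ped <= config$lesion_threshold] <- 0L
  rd[rd <= config$lesion_threshold] <- 0L
  rpe <- config$baseline_rpe_depth + tilt_field(config) - ped
  labels <- matrix("NEITHER", config$n_bscans, config$n_ascans)
  labels[rd > 0] <- "RD"
  labels[ped > 0] <- "PED"
  structure(
    list(ped_height = ped, rd_height = rd, rpe_depth_true = rpe,
         label_map = signature_label_map(labels, eye_id = sprintf("syn-seed%d", config$seed)),
         config = config),
    class = "scene_ground_truth")
}

# Noiseless reflectivity profile of one A-scan column.
# anchor: depth of the RPE band center; bm: resting Bruch's membrane depth.
render_column <- function(cfg, anchor, bm, ped, rd, band) {
  p <- rep(band["vitreous"], cfg$depth)
  clip_idx <- function(lo, hi) {
    lo <- max(1L, as.integer(lo)); hi <- min(cfg$depth, as.integer(hi))
    if (lo > hi) integer(0) else lo:hi
  }
  # choroid below the resting BM position (or below complex when no PED)
  p[clip_idx(bm + 20, cfg$depth)] <- band["choroid"]
  # neurosensory retina, shifted anteriorly by the RD cleft height
  p[clip_idx(anchor - rd - 119, anchor - rd - 60)] <- band["inner_retina"]
  p[clip_idx(anchor - rd - 59, anchor - rd - 20)] <- band["onl"]
  if (rd > 0)  # serous cleft between retina and the outer complex
    p[clip_idx(anchor - 19 - rd, anchor - 20)] <- cfg$fluid_reflectivity
  # hyperreflective outer complex, anchored to the RPE
  p[clip_idx(anchor - 19, anchor - 5)] <- band["ez_complex"]
  p[clip_idx(anchor + 5, anchor + 19)] <- band["choriocapillaris"]
  p[clip_idx(anchor - 4, anchor + 4)] <- band["rpe"]
  if (ped > 0) {
    # serous cavity of the full elevation height between the elevated complex
    # and the bared BM line resting at baseline
    p[clip_idx(anchor + 20, bm + 19)] <- cfg$fluid_reflectivity
    p[clip_idx(bm + 20, bm + 21)] <- cfg$bm_reflectivity
    p[clip_idx(bm + 22, cfg$depth)] <- band["choroid"]
  }
  p
}

#' Render a synthetic OCT volume from a scene
#'
#' Draws the layered band profile for every A-scan, anchored at the true RPE
#' depth, inserting a hyporeflective cavity under elevated RPE (PED) and a
#' hyporeflective cleft between retina and RPE (RD), then multiplies by
#' mean-1 gamma speckle (seeded from the config) and clips to `[0, 1]`.
#'
#' @param scene A [make_scene()] result.
#' @param config The matching [scene_config()] (default: the one stored in
#'   the scene).
#' @return An [oct_volume()].
#' @export
render_volume <- function(scene, config = scene$config) {
  stopifnot(inherits(scene, "scene_ground_truth"), inherits(config, "scene_config"))
  if (!identical(dim(scene$ped_height), c(config$n_bscans, config$n_ascans)))
    abort_validation("scene and config geometry disagree")
  band <- stats::setNames(config$layer_spec$reflectivity, config$layer_spec$band)
  tilt <- tilt_field(config)
  vol <- array(0, dim = c(config$n_bscans, config$n_ascans, config$depth))
  for (b in seq_len(config$n_bscans)) {
    page <- matrix(0, config$n_ascans, config$depth)
    for (a in seq_len(config$n_ascans)) {
      page[a, ] <- render_column(
        config,
        anchor = scene$rpe_depth_true[b, a],
        bm = config$baseline_rpe_depth + tilt[b, a],
        ped = scene$ped_height[b, a],
        rd = scene$rd_height[b, a],
        band = band)
    }
    vol[b, , ] <- page
  }
  if (config$speckle_shape > 0) {
    noise <- with_seed(config$seed,
      stats::rgamma(length(vol), shape = config$speckle_shape,
                    rate = config$speckle_shape))
    vol <- vol * noise
  }
  vol[vol > 1] <- 1
  vol[vol < 0] <- 0
  oct_volume(vol, eye_id = scene$label_map$eye_id)
}

random_bumps <- function(n, n_b, n_a, sigma_b_range, sigma_a_range, height_range) {
  lapply(seq_len(n), function(i) c(
    stats::runif(1, 0.15 * n_b, 0.85 * n_b),
    stats::runif(1, 0.15 * n_a, 0.85 * n_a),
    stats::runif(1, sigma_b_range[1], sigma_b_range[2]),
    stats::runif(1, sigma_a_range[1], sigma_a_range[2]),
    stats::runif(1, height_range[1], height_range[2])))
}

#' Generate a cohort of synthetic eyes
#'
#' Per-eye seeds are derived deterministically from the master seed; lesion
#' number, position, lateral extent, peak height, and axial tilt are
#' randomized per eye (1-3 PED domes of 8-28 px peak elevation, 1-2 broader
#' RD blisters of 10-40 px, tilts up to about 0.1 px per lateral px). Each
#' eye contains all three classes.
#'
#' @param n_eyes Number of eyes (>= 1).
#' @param template A [scene_config()] providing geometry, bands, noise and
#'   threshold; its bump lists are replaced per eye unless
#'   `randomize_lesions = FALSE`.
#' @param seed Master seed.
#' @param randomize_lesions If `FALSE`, keep the template's bump lists and
#'   tilt for every eye (only speckle varies per eye).
#' @return List of length `n_eyes`; each element has `volume`
#'   ([oct_volume()]), `label_map` ([signature_label_map()]), and `scene`
#'   (the [make_scene()] ground truth).
#' @export
make_cohort <- function(n_eyes, template = scene_config(), seed = template$seed,
                        randomize_lesions = TRUE) {
  if (!is_count(n_eyes)) abort_validation("n_eyes must be a positive integer")
  lapply(seq_len(n_eyes), function(e) {
    es <- derive_seed(seed, e)
    drawn <- if (!randomize_lesions) {
      list(ped = template$ped_bumps, rd = template$rd_bumps, tilt = template$tilt)
    } else with_seed(es, {
      sb_ped <- c(0.05, 0.12) * template$n_bscans
      sa_ped <- c(0.05, 0.12) * template$n_ascans
      sb_rd <- c(0.10, 0.22) * template$n_bscans
      sa_rd <- c(0.10, 0.22) * template$n_ascans
      list(ped = random_bumps(sample(1:3, 1), template$n_bscans, template$n_ascans,
                              sb_ped, sa_ped, c(8, 28)),
           rd = random_bumps(sample(1:2, 1), template$n_bscans, template$n_ascans,
                             sb_rd, sa_rd, c(10, 40)),
           tilt = c(stats::runif(1, -0.08, 0.08), stats::runif(1, -0.04, 0.04)))
    })
    cfg <- template
    cfg$ped_bumps <- drawn$ped
    cfg$rd_bumps <- drawn$rd
    cfg$tilt <- drawn$tilt
    cfg$seed <- derive_seed(es, 99)
    check_scene_bounds(cfg)
    scene <- make_scene(cfg)
    eye_id <- sprintf("syn%03d", e)
    scene$label_map$eye_id <- eye_id
    vol <- render_volume(scene, cfg)
    vol$eye_id <- eye_id
    list(volume = vol, label_map = scene$label_map, scene = scene)
  })
}

#' Benchmark scene template at reduced geometry
#'
#' The package's standard synthetic study conditions: 64 B-scans x 128 A-scans
#' x 512 depth px with the RPE resting at depth 280, default bands, gamma-4
#' speckle, and the default 2-px lesion threshold. All end-to-end regression
#' figures quoted by the package are computed on cohorts built from this
#' template.
#'
#' @param seed Seed stored in the template.
#' @return A [scene_config()].
#' @export
benchmark_scene_config <- function(seed = 1L) {
  scene_config(n_bscans = 64, n_ascans = 128, depth = 512,
               baseline_rpe_depth = 280, seed = seed)
}

#' Read or write a scene configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_scene_config` returns a [scene_config()].
#' @export
read_scene_config <- function(path) {
  y <- yaml::read_yaml(path)
  ls <- if (is.null(y$layer_spec)) default_layer_spec() else {
    d <- as.data.frame(do.call(rbind, lapply(y$layer_spec, function(r)
      data.frame(band = r$band, lo = as.numeric(r$lo), hi = as.numeric(r$hi),
                 reflectivity = r$reflectivity))))
    d
  }
  scene_config(
    n_bscans = y$n_bscans %||% 256, n_ascans = y$n_ascans %||% 512,
    depth = y$depth %||% 992,
    baseline_rpe_depth = y$baseline_rpe_depth %||% 550,
    layer_spec = ls,
    ped_bumps = lapply(y$ped_bumps, as.numeric),
    rd_bumps = lapply(y$rd_bumps, as.numeric),
    lesion_threshold = y$lesion_threshold %||% 2,
    speckle_shape = y$speckle_shape %||% 4,
    tilt = as.numeric(y$tilt %||% c(0, 0)),
    fluid_reflectivity = y$fluid_reflectivity %||% 0.05,
    bm_reflectivity = y$bm_reflectivity %||% 0.28,
    seed = y$seed %||% 1)
}

#' @rdname read_scene_config
#' @param config A [scene_config()].
#' @export
write_scene_config <- function(config, path) {
  stopifnot(inherits(config, "scene_config"))
  out <- config
  class(out) <- NULL
  out$layer_spec <- lapply(seq_len(nrow(config$layer_spec)), function(i)
    as.list(config$layer_spec[i, ]))
  out$ped_bumps <- lapply(config$ped_bumps, as.numeric)
  out$rd_bumps <- lapply(config$rd_bumps, as.numeric)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
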