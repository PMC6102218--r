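test_that("a lesion-free scene is entirely NEITHER with the RPE at baseline", {
  cfg <- scene_config(n_bscans = 4, n_ascans = 6, depth = 256,
                      baseline_rpe_depth = 180, speckle_shape = 0)
  scene <- make_scene(cfg)
  expect_true(all(scene$ped_height == 0))
  expect_true(all(scene$rd_height == 0))
  expect_true(all(scene$label_map$labels == "NEITHER"))
  expect_true(all(scene$rpe_depth_true == 180))
})

test_that("lesion labels match a per-pixel Gaussian oracle under precedence", {
  cfg <- tiny_scene_config()
  scene <- make_scene(cfg)
  thr <- cfg$lesion_threshold
  for (b in 1:cfg$n_bscans) for (a in 1:cfg$n_ascans) {
    gp <- sum(vapply(cfg$ped_bumps, function(bp)
      bp[5] * exp(-(b - bp[1])^2 / (2 * bp[3]^2) - (a - bp[2])^2 / (2 * bp[4]^2)),
      numeric(1)))
    gr <- sum(vapply(cfg$rd_bumps, function(bp)
      bp[5] * exp(-(b - bp[1])^2 / (2 * bp[3]^2) - (a - bp[2])^2 / (2 * bp[4]^2)),
      numeric(1)))
    ph <- if (round(gp) > thr) round(gp) else 0
    rh <- if (round(gr) > thr) round(gr) else 0
    expect_identical(scene$ped_height[b, a], ph)
    expect_identical(scene$rd_height[b, a], rh)
    want <- if (ph > thr) "PED" else if (rh > thr) "RD" else "NEITHER"
    expect_identical(scene$label_map$labels[b, a], want)
  }
})

test_that("label map is exactly the thresholded height fields for random scenes", {
  for (seed in 1:5) {
    set.seed(seed)
    cfg <- scene_config(
      n_bscans = 10, n_ascans = 20, depth = 256, baseline_rpe_depth = 170,
      ped_bumps = list(c(runif(1, 2, 9), runif(1, 3, 18), runif(1, 1, 3),
                         runif(1, 2, 5), runif(1, 5, 25))),
      rd_bumps = list(c(runif(1, 2, 9), runif(1, 3, 18), runif(1, 1, 3),
                        runif(1, 2, 5), runif(1, 5, 30))),
      speckle_shape = 0, seed = seed)
    sc <- make_scene(cfg)
    thr <- cfg$lesion_threshold
    expect_identical(sc$label_map$labels == "PED", sc$ped_height > thr)
    expect_identical(sc$label_map$labels == "RD",
                     sc$rd_height > thr & sc$ped_height <= thr)
    expect_identical(sc$rpe_depth_true,
                     cfg$baseline_rpe_depth - sc$ped_height + 0 * sc$ped_height)
  }
})

test_that("scene construction is deterministic and validates bump placement", {
  cfg <- tiny_scene_config(seed = 9)
  expect_identical(make_scene(cfg), make_scene(cfg))
  expect_validation_error(
    scene_config(n_bscans = 8, n_ascans = 8, depth = 256, baseline_rpe_depth = 180,
                 ped_bumps = list(c(20, 4, 2, 2, 5))))
  expect_validation_error(  # profile would not fit in depth
    scene_config(n_bscans = 4, n_ascans = 4, depth = 128, baseline_rpe_depth = 100))
  expect_validation_error(  # RPE must stay the brightest band
    {ls <- default_layer_spec(); ls$reflectivity[ls$band == "choroid"] <- 0.99
     scene_config(depth = 992, layer_spec = ls)})
})

test_that("noiseless renders anchor the brightest band and the 40-px search at the true RPE", {
  cfg <- tiny_scene_config(speckle_shape = 0, tilt = c(0.05, 0))
  scene <- make_scene(cfg)
  vol <- render_volume(scene, cfg)
  rpe_refl <- cfg$layer_spec$reflectivity[cfg$layer_spec$band == "rpe"]
  for (b in 1:cfg$n_bscans) for (a in 1:cfg$n_ascans) {
    col <- vol$intensities[b, a, ]
    if (scene$label_map$labels[b, a] == "NEITHER") {
      # depth-wise intensity maximum falls inside the RPE band
      expect_true(abs(which.max(col) - scene$rpe_depth_true[b, a]) <= 4)
      expect_equal(max(col), rpe_refl)
    }
    expect_lte(abs(locate_rpe(col, 40) - scene$rpe_depth_true[b, a]), 2)
  }
})

test_that("RD clefts and PED cavities are hyporeflective relative to the RPE", {
  cfg <- tiny_scene_config(speckle_shape = 0)
  scene <- make_scene(cfg)
  vol <- render_volume(scene, cfg)
  rd_pos <- which(scene$label_map$labels == "RD" & scene$rd_height > 5, arr.ind = TRUE)
  ped_pos <- which(scene$label_map$labels == "PED" & scene$ped_height > 5, arr.ind = TRUE)
  expect_gt(nrow(rd_pos), 0); expect_gt(nrow(ped_pos), 0)
  b <- rd_pos[1, 1]; a <- rd_pos[1, 2]
  r <- scene$rpe_depth_true[b, a]; h <- scene$rd_height[b, a]
  cleft <- vol$intensities[b, a, (r - 19 - h):(r - 20)]
  rpe_band <- vol$intensities[b, a, (r - 4):(r + 4)]
  expect_lt(mean(cleft), mean(rpe_band))
  b <- ped_pos[1, 1]; a <- ped_pos[1, 2]
  r <- scene$rpe_depth_true[b, a]; h <- scene$ped_height[b, a]
  cavity <- vol$intensities[b, a, (r + 20):(r + 19 + h)]
  expect_lt(mean(cavity), 0.1)
  # zero reflectivity everywhere renders a zero volume
  cfg0 <- cfg
  cfg0$layer_spec$reflectivity <- c(0, 0, 0, 0, 1e-9, 0, 0)
  cfg0$fluid_reflectivity <- 0; cfg0$bm_reflectivity <- 0
  expect_lt(max(render_volume(make_scene(cfg0), cfg0)$intensities), 1e-8)
})

test_that("speckle is mean-preserving at unclipped voxels", {
  cfg <- scene_config(n_bscans = 2, n_ascans = 4, depth = 160,
                      baseline_rpe_depth = 130, speckle_shape = 4, seed = 1)
  scene <- make_scene(cfg)
  cfg_noiseless <- cfg; cfg_noiseless$speckle_shape <- 0
  clean <- render_volume(scene, cfg_noiseless)$intensities
  # ONL voxel (dark band): clipping at 1 is negligible there
  b <- 1; a <- 2; d <- cfg$baseline_rpe_depth - 40
  expect_equal(clean[b, a, d], 0.12)
  draws <- vapply(1:200, function(s) {
    cfg$seed <- s
    render_volume(scene, cfg)$intensities[b, a, d]
  }, numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - clean[b, a, d]), 3 * se)
})

test_that("cohorts are seed-deterministic with per-eye variation and exact totals", {
  tpl <- scene_config(n_bscans = 6, n_ascans = 12, depth = 360,
                      baseline_rpe_depth = 250)
  c1 <- make_cohort(3, tpl, seed = 21)
  c2 <- make_cohort(3, tpl, seed = 21)
  expect_identical(lapply(c1, function(e) e$volume$intensities),
                   lapply(c2, function(e) e$volume$intensities))
  expect_false(identical(c1[[1]]$volume$intensities, c1[[2]]$volume$intensities))
  ct <- catalog(lapply(c1, `[[`, "volume"), lapply(c1, `[[`, "label_map"))
  expect_equal(ct$total_ascans, 3 * 6 * 12)
  expect_equal(sum(ct$per_class_label_counts), ct$total_ascans)
  # a lesion-free template passed through unchanged yields an all-NEITHER map
  one <- make_cohort(1, scene_config(n_bscans = 4, n_ascans = 6, depth = 256,
                                     baseline_rpe_depth = 170), seed = 2,
                     randomize_lesions = FALSE)
  expect_true(all(one[[1]]$label_map$labels == "NEITHER"))
})

test_that("scene config YAML round trip preserves the configuration", {
  cfg <- tiny_scene_config(seed = 4, speckle_shape = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene_config(cfg, path)
  back <- read_scene_config(path)
  expect_equal(back$ped_bumps, cfg$ped_bumps)
  expect_equal(back$baseline_rpe_depth, cfg$baseline_rpe_depth)
  expect_identical(make_scene(back)$label_map$labels, make_scene(cfg)$label_map$labels)
})
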