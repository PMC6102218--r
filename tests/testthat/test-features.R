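# Exhaustive maximal-mean-window search, the oracle for locate_rpe.
brute_locate <- function(x, w) {
  means <- vapply(seq_len(length(x) - w + 1), function(s) mean(x[s:(s + w - 1)]),
                  numeric(1))
  s <- which.max(means)
  s + (w - 1) %/% 2
}

test_that("locate_rpe finds the maximal mean window with the floor/tie conventions", {
  # unique 40-px plateau at depths 401..440 -> center 420
  x <- numeric(992); x[401:440] <- 1
  expect_identical(locate_rpe(x, 40), 420L)
  # constant vector: tie broken to the first window, center 20
  expect_identical(locate_rpe(rep(0.3, 992), 40), 20L)
  expect_validation_error(locate_rpe(numeric(10), 40))
  # random vectors against the exhaustive oracle, several window sizes
  set.seed(31)
  for (rep_i in 1:5) {
    x <- runif(992)
    expect_identical(locate_rpe(x, 40), as.integer(brute_locate(x, 40)))
  }
  y <- runif(60)
  for (w in c(1, 2, 3, 7, 40, 59, 60))
    expect_identical(locate_rpe(y, w), as.integer(brute_locate(y, w)))
})

test_that("volume RPE maps equal per-column searches and median smoothing fixes outliers", {
  vol <- random_volume(3, 8, 64, seed = 12)
  par0 <- feature_params(lateral_smooth = 0)
  got <- locate_rpe_volume(vol, par0)
  for (b in 1:3) for (a in 1:8)
    expect_identical(got[b, a], locate_rpe(vol$intensities[b, a, ], 40))
  # single outlier column among flat neighbors is replaced by the median
  arr <- array(0, c(1, 9, 100))
  arr[1, , 30:69] <- 1   # 40-px plateau -> every column locates depth 49
  arr[1, 5, ] <- 0; arr[1, 5, 5:44] <- 1  # outlier column locates depth 24
  v2 <- oct_volume(arr)
  raw <- locate_rpe_volume(v2, par0)
  expect_identical(raw[1, 5], 24L)
  expect_identical(raw[1, 4], 49L)
  sm <- locate_rpe_volume(v2, feature_params(lateral_smooth = 5))
  expect_identical(sm[1, 5], 49L)
})

test_that("RPE recovery on synthetic data is tight noiseless and robust to speckle", {
  cfg <- tiny_scene_config(speckle_shape = 0, tilt = c(0.04, 0.02))
  scene <- make_scene(cfg)
  pp <- preprocess_volume(render_volume(scene, cfg))
  err <- abs(locate_rpe_volume(pp) - scene$rpe_depth_true)
  expect_lte(max(err), 2)
  cfg$speckle_shape <- 4
  pps <- preprocess_volume(render_volume(scene, cfg))
  errs <- abs(locate_rpe_volume(pps) - scene$rpe_depth_true)
  expect_lte(median(errs), 5)
})

test_that("crop_ascan returns the inclusive anchored window with zero padding", {
  par <- feature_params()
  x <- seq_len(992) / 992
  f <- crop_ascan(x, 501, par)
  expect_length(f, 401)
  expect_identical(feature_length(par), 401L)
  expect_equal(f, x[201:601])
  # anterior padding: rpe at 101 leaves 200 leading zeros
  f2 <- crop_ascan(x, 101, par)
  expect_true(all(f2[1:200] == 0))
  expect_equal(f2[201:401], x[1:201])
  # posterior padding: rpe at 951 leaves 59 trailing zeros
  f3 <- crop_ascan(x, 951, par)
  expect_true(all(f3[343:401] == 0))
  expect_equal(f3[1:342], x[651:992])
  expect_validation_error(crop_ascan(x, 0, par))
  # exact length for every anchor position on a short profile
  y <- runif(50)
  p2 <- feature_params(anterior_px = 7, posterior_px = 4)
  for (r in 1:50) expect_length(crop_ascan(y, r, p2), 12)
})

test_that("normalization standardizes, inverts, and matches a two-pass oracle", {
  # forced arithmetic: column c(0, 2) has mean 1, population variance 1
  m <- cbind(c(0, 2), c(5, 5))
  norm <- fit_normalizer(m)
  z <- apply_normalizer(norm, m)
  expect_equal(z[, 1], c(-1, 1), tolerance = 1e-6)
  expect_true(all(z[, 2] == 0))  # constant column maps to zero
  set.seed(77)
  x <- matrix(runif(100 * 25), 100, 25)
  nr <- fit_normalizer(x)
  zx <- apply_normalizer(nr, x)
  # two-pass loop oracle for the resulting moments
  for (j in seq(1, 25, by = 6)) {
    mu <- sum(x[, j]) / 100
    v <- sum((x[, j] - mu)^2) / 100
    expect_lt(abs(mean(zx[, j])), 1e-8)
    expect_lt(abs(sum((zx[, j] - mean(zx[, j]))^2) / 100 - v / (v + nr$epsilon)), 1e-3)
  }
  expect_true(all(abs(colMeans(zx)) < 1e-8))
  expect_true(all(abs(colMeans(zx^2) - colMeans(zx)^2 - 1) < 1e-3))
  expect_equal(invert_normalizer(nr, zx), x, tolerance = 1e-10)
  expect_validation_error(fit_normalizer(matrix(numeric(0), 0, 3)))
})

test_that("build_dataset keeps exactly the labeled A-scans with their positions", {
  vol <- random_volume(4, 6, 64, seed = 3, eye_id = "eyeA")
  lab <- matrix("UNLABELED", 4, 6)
  expect_identical(nrow(build_dataset(list(vol), list(signature_label_map(lab)),
                                      preprocess_params(), feature_params())$features), 0L)
  set.seed(9)
  cells <- sample(24, 15)
  lab[cells[1:7]] <- "PED"; lab[cells[8:12]] <- "RD"; lab[cells[13:15]] <- "NEITHER"
  map <- signature_label_map(lab, eye_id = "eyeA")
  par <- feature_params(anterior_px = 10, posterior_px = 5, lateral_smooth = 0)
  fs <- build_dataset(list(vol), list(map), preprocess_params(), par)
  expect_identical(as.vector(table(fs$labels)), c(7L, 5L, 3L))
  expect_identical(ncol(fs$features), 16L)
  expect_false(anyDuplicated(fs$positions[c("bscan", "ascan")]) > 0)
  # row content equals a direct crop of the preprocessed volume
  pp <- preprocess_volume(vol, preprocess_params())
  rpe <- locate_rpe_volume(pp, par)
  i <- 5
  b <- fs$positions$bscan[i]; a <- fs$positions$ascan[i]
  expect_equal(fs$features[i, ], crop_ascan(pp$intensities[b, a, ], rpe[b, a], par))
  expect_identical(fs$rpe_depths[i], rpe[b, a])
  expect_identical(fs$labels[i], factor(map$labels[b, a], levels = signature_classes())[1])
  # per-class counts cross-check against the catalog on a synthetic cohort
  cfg <- tiny_scene_config()
  cohort <- make_cohort(2, cfg, seed = 6, randomize_lesions = FALSE)
  fs2 <- build_dataset(lapply(cohort, `[[`, "volume"),
                       lapply(cohort, `[[`, "label_map"),
                       preprocess_params(), feature_params(anterior_px = 30, posterior_px = 10))
  ct <- catalog(lapply(cohort, `[[`, "volume"), lapply(cohort, `[[`, "label_map"))
  expect_identical(as.integer(table(fs2$labels)),
                   as.integer(ct$per_class_label_counts[signature_classes()]))
  expect_validation_error(build_dataset(list(vol), list()))
})

test_that("feature sets and normalizers serialize to plain-text artifacts", {
  fs <- counted_feature_set(4, 3, 5, width = 6, seed = 2)
  stem <- file.path(withr::local_tempdir(), "fs")
  write_feature_set(fs, stem)
  tab <- read.csv(paste0(stem, ".samples.csv"))
  expect_identical(nrow(tab), 12L)
  expect_identical(tab$label, as.character(fs$labels))
  con <- file(paste0(stem, ".features.bin"), "rb")
  vals <- readBin(con, "double", n = 12 * 6)
  close(con)
  expect_equal(matrix(vals, 12, 6, byrow = TRUE), fs$features)
  norm <- fit_normalizer(fs$features)
  npath <- withr::local_tempfile(fileext = ".json")
  save_normalizer(norm, npath)
  back <- load_normalizer(npath)
  expect_equal(back$mean, norm$mean)
  expect_equal(apply_normalizer(back, fs$features), apply_normalizer(norm, fs$features))
})
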