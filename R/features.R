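#' Feature extraction parameters
#'
#' The RPE is located per A-scan as the center of the 40-px depth window with
#' maximal mean intensity; each A-scan is then cropped to 300 px anterior and
#' 100 px posterior of the RPE (inclusive of the RPE pixel), giving
#' fixed-length reflectivity feature vectors of length
#' `anterior_px + posterior_px + 1` (401 by default).
#'
#' @param rpe_window Length of the sliding mean window (default 40).
#' @param anterior_px Pixels kept anterior (shallower) of the RPE (default 300).
#' @param posterior_px Pixels kept posterior (deeper) of the RPE (default 100).
#' @param lateral_smooth Odd width of the median smoothing of the RPE depth
#'   along the A-scan axis within each B-scan, or 0 to disable (default 5).
#' @return An object of class `feature_params`.
#' @export
feature_params <- function(rpe_window = 40, anterior_px = 300,
                           posterior_px = 100, lateral_smooth = 5) {
  if (!is_count(rpe_window)) abort_validation("rpe_window must be >= 1")
  if (anterior_px < 0 || posterior_px < 0)
    abort_validation("anterior_px and posterior_px must be >= 0")
  if (lateral_smooth != 0 && (!is_count(lateral_smooth) || lateral_smooth %% 2 != 1))
    abort_validation("lateral_smooth must be 0 or an odd integer")
  structure(list(rpe_window = as.integer(rpe_window),
                 anterior_px = as.integer(anterior_px),
                 posterior_px = as.integer(posterior_px),
                 lateral_smooth = as.integer(lateral_smooth)),
            class = "feature_params")
}

#' @rdname feature_params
#' @param params A `feature_params` object.
#' @export
feature_length <- function(params = feature_params()) {
  params$anterior_px + params$posterior_px + 1L
}

#' Locate the RPE in one A-scan
#'
#' Slides a contiguous window of `window` depth pixels along the reflectivity
#' profile and returns the center index (floor convention,
#' `start + (window - 1) %/% 2`, 1-based) of the window with maximal mean
#' intensity. Ties resolve to the smallest start index.
#'
#' @param ascan Numeric reflectivity vector.
#' @param window Window length (default 40); must not exceed `length(ascan)`.
#' @return Integer depth index of the estimated RPE.
#' @export
locate_rpe <- function(ascan, window = 40) {
  n <- length(ascan)
  if (!is_count(window) || window > n)
    abort_validation("window (%d) must lie in [1, length(ascan) = %d]", window, n)
  cs <- cumsum(as.numeric(ascan))
  sums <- cs[window:n] - c(0, cs[seq_len(n - window)])
  # ties (within floating-point slack of the running-sum trick) resolve to
  # the smallest start index
  tol <- 1e-9 * max(abs(sums), 1)
  start <- which(sums > max(sums) - tol)[1]
  as.integer(start + (window - 1L) %/% 2L)
}

#' Locate the RPE across a whole volume
#'
#' Runs [locate_rpe()] on every A-scan, then (optionally) median-smooths the
#' resulting depth map along the A-scan axis within each B-scan to suppress
#' isolated outliers.
#'
#' @param vol An [oct_volume()] (typically preprocessed).
#' @param params A [feature_params()].
#' @return Integer matrix `(n_bscans, n_ascans)` of RPE depth indices.
#' @export
locate_rpe_volume <- function(vol, params = feature_params()) {
  stopifnot(inherits(vol, "oct_volume"), inherits(params, "feature_params"))
  w <- params$rpe_window
  if (w > vol$depth) abort_validation("rpe_window exceeds volume depth")
  half <- (w - 1L) %/% 2L
  out <- matrix(0L, vol$n_bscans, vol$n_ascans)
  for (b in seq_len(vol$n_bscans)) {
    page <- vol$intensities[b, , ]                        # (ascan x depth)
    cs <- t(apply(page, 1, cumsum))
    sums <- cs[, w:vol$depth, drop = FALSE] -
      cbind(0, cs[, seq_len(vol$depth - w), drop = FALSE])
    rmax <- apply(sums, 1, max)
    tol <- 1e-9 * pmax(abs(rmax), 1)
    starts <- max.col(sums > rmax - tol, ties.method = "first")  # first tied start
    depths <- as.integer(starts + half)
    if (params$lateral_smooth >= 3 && length(depths) >= params$lateral_smooth)
      depths <- as.integer(stats::runmed(depths, params$lateral_smooth,
                                         endrule = "median"))
    out[b, ] <- depths
  }
  out
}

#' Crop an A-scan around the RPE
#'
#' Extracts depths `[rpe_depth - anterior_px, rpe_depth + posterior_px]`
#' inclusive. Positions outside the profile are zero-padded so the result
#' always has length [feature_length()].
#'
#' @param ascan Numeric reflectivity vector.
#' @param rpe_depth RPE depth index in `[1, length(ascan)]`.
#' @param params A [feature_params()].
#' @return Numeric vector of length `anterior_px + posterior_px + 1`.
#' @export
crop_ascan <- function(ascan, rpe_depth, params = feature_params()) {
  n <- length(ascan)
  if (!is_count(rpe_depth) || rpe_depth > n)
    abort_validation("rpe_depth must lie in [1, %d]", n)
  idx <- (rpe_depth - params$anterior_px):(rpe_depth + params$posterior_px)
  out <- numeric(length(idx))
  ok <- idx >= 1 & idx <= n
  out[ok] <- ascan[idx[ok]]
  out
}

#' Per-feature standardization
#'
#' `fit_normalizer` records the per-column mean and population variance of a
#' feature matrix; `apply_normalizer` maps features to
#' `(x - mean) / sqrt(var + epsilon)`, so each fitted column has mean 0 and
#' variance 1 (constant columns map to 0). The normalizer is meant to be fit
#' on the training split only and then applied unchanged to validation, test,
#' and unseen data.
#'
#' @param features Numeric matrix (samples x features).
#' @param epsilon Variance floor (default 1e-8).
#' @return `fit_normalizer` returns an object of class `feature_normalizer`
#'   with fields `mean`, `var`, `epsilon`.
#' @export
fit_normalizer <- function(features, epsilon = 1e-8) {
  if (!is.matrix(features) || nrow(features) < 1)
    abort_validation("fit_normalizer needs a non-empty feature matrix")
  mu <- colMeans(features)
  v <- colMeans(features^2) - mu^2
  v[v < 0] <- 0  # guard tiny negative round-off
  structure(list(mean = mu, var = v, epsilon = epsilon),
            class = "feature_normalizer")
}

#' @rdname fit_normalizer
#' @param norm A `feature_normalizer`.
#' @export
apply_normalizer <- function(norm, features) {
  stopifnot(inherits(norm, "feature_normalizer"))
  if (ncol(features) != length(norm$mean))
    abort_validation("feature width (%d) does not match normalizer (%d)",
                     ncol(features), length(norm$mean))
  sweep(sweep(features, 2, norm$mean, "-"), 2, sqrt(norm$var + norm$epsilon), "/")
}

#' @rdname fit_normalizer
#' @param normalized Matrix previously produced by `apply_normalizer`.
#' @export
invert_normalizer <- function(norm, normalized) {
  stopifnot(inherits(norm, "feature_normalizer"))
  sweep(sweep(normalized, 2, sqrt(norm$var + norm$epsilon), "*"), 2, norm$mean, "+")
}

#' @rdname fit_normalizer
#' @param path JSON path for saving/loading a fitted normalizer.
#' @export
save_normalizer <- function(norm, path) {
  stopifnot(inherits(norm, "feature_normalizer"))
  jsonlite::write_json(unclass(norm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fit_normalizer
#' @export
load_normalizer <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(j$mean), var = as.numeric(j$var),
                 epsilon = as.numeric(j$epsilon)),
            class = "feature_normalizer")
}

#' Labeled feature set container
#'
#' @param features Numeric matrix (samples x feature length), raw (not
#'   normalized) RPE-anchored crops.
#' @param labels Factor (or character) over [signature_classes()].
#' @param positions Data frame with columns `eye_id`, `bscan`, `ascan`.
#' @param rpe_depths Integer vector of located RPE depths.
#' @return Object of class `labeled_feature_set`.
#' @export
labeled_feature_set <- function(features, labels, positions, rpe_depths) {
  labels <- factor(as.character(labels), levels = signature_classes())
  if (anyNA(labels)) abort_validation("labels must be PED, RD, or NEITHER")
  n <- nrow(features)
  if (length(labels) != n || nrow(positions) != n || length(rpe_depths) != n)
    abort_validation("features, labels, positions, rpe_depths must agree in length")
  structure(list(features = features, labels = labels,
                 positions = positions, rpe_depths = as.integer(rpe_depths)),
            class = "labeled_feature_set")
}

#' @export
print.labeled_feature_set <- function(x, ...) {
  cat(sprintf("<labeled_feature_set> %d samples x %d features (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Subset a labeled feature set by row index
#'
#' @param fs A [labeled_feature_set()].
#' @param idx Integer row indices.
#' @return A [labeled_feature_set()].
#' @export
subset_feature_set <- function(fs, idx) {
  stopifnot(inherits(fs, "labeled_feature_set"))
  labeled_feature_set(fs$features[idx, , drop = FALSE], fs$labels[idx],
                      fs$positions[idx, , drop = FALSE], fs$rpe_depths[idx])
}

# Vectorized crop of selected en face positions of one preprocessed volume.
extract_feature_rows <- function(vol, rpe_map, sel, params) {
  off <- -params$anterior_px:params$posterior_px
  feats <- matrix(0, nrow(sel), length(off))
  depths <- integer(nrow(sel))
  row0 <- 0
  for (b in sort(unique(sel[, 1]))) {
    cols <- sel[sel[, 1] == b, 2]
    page <- vol$intensities[b, , ]                 # (ascan x depth)
    idx <- outer(rpe_map[b, cols], off, "+")
    ok <- idx >= 1 & idx <= vol$depth
    idxc <- pmin(pmax(idx, 1L), vol$depth)
    lin <- (idxc - 1L) * vol$n_ascans + cols       # column-recycled gather
    f <- matrix(page[lin], nrow = length(cols))
    f[!ok] <- 0
    feats[row0 + seq_along(cols), ] <- f
    depths[row0 + seq_along(cols)] <- rpe_map[b, cols]
    row0 <- row0 + length(cols)
  }
  list(features = feats, rpe_depths = depths)
}

#' Build a labeled feature set from volumes and label maps
#'
#' For every A-scan labeled PED, RD, or NEITHER (UNLABELED/equivocal A-scans
#' are excluded), preprocesses the volume, locates the RPE, and extracts the
#' raw RPE-anchored crop, retaining the anatomical position of each sample.
#'
#' @param volumes List of [oct_volume()].
#' @param label_maps List of [signature_label_map()], aligned with `volumes`.
#' @param preprocess A [preprocess_params()].
#' @param params A [feature_params()].
#' @return A [labeled_feature_set()].
#' @export
build_dataset <- function(volumes, label_maps,
                          preprocess = preprocess_params(),
                          params = feature_params()) {
  if (length(volumes) != length(label_maps))
    abort_validation("volumes and label_maps differ in length")
  parts <- vector("list", length(volumes))
  for (i in seq_along(volumes)) {
    vol <- volumes[[i]]; map <- label_maps[[i]]
    if (!identical(as.integer(dim(map$labels)), c(vol$n_bscans, vol$n_ascans)))
      abort_validation("eye %d: label map shape does not match volume en face plane", i)
    pp <- preprocess_volume(vol, preprocess)
    rpe_map <- locate_rpe_volume(pp, params)
    sel <- which(map$labels != "UNLABELED", arr.ind = TRUE)
    if (nrow(sel) == 0) {
      parts[[i]] <- NULL
      next
    }
    sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
    ex <- extract_feature_rows(pp, rpe_map, sel, params)
    parts[[i]] <- list(
      features = ex$features,
      labels = map$labels[sel],
      positions = data.frame(eye_id = vol$eye_id, bscan = sel[, 1],
                             ascan = sel[, 2], row.names = NULL),
      rpe_depths = ex$rpe_depths)
  }
  parts <- Filter(Negate(is.null), parts)
  if (!length(parts)) {
    return(labeled_feature_set(matrix(0, 0, feature_length(params)),
                               character(0),
                               data.frame(eye_id = character(0), bscan = integer(0),
                                          ascan = integer(0)),
                               integer(0)))
  }
  labeled_feature_set(
    do.call(rbind, lapply(parts, `[[`, "features")),
    unlist(lapply(parts, `[[`, "labels")),
    do.call(rbind, lapply(parts, `[[`, "positions")),
    unlist(lapply(parts, `[[`, "rpe_depths")))
}

#' Write a labeled feature set to disk
#'
#' Features go to a raw float64 array with a JSON sidecar; the sample table
#' (eye, position, label, RPE depth) goes to CSV alongside.
#'
#' @param fs A [labeled_feature_set()].
#' @param stem Path stem; writes `<stem>.features.bin`, its `.json` sidecar,
#'   and `<stem>.samples.csv`.
#' @return Invisibly, `stem`.
#' @export
write_feature_set <- function(fs, stem) {
  stopifnot(inherits(fs, "labeled_feature_set"))
  bin <- paste0(stem, ".features.bin")
  con <- file(bin, "wb")
  writeBin(as.vector(t(fs$features)), con, size = 8)
  close(con)
  jsonlite::write_json(list(shape = dim(fs$features), dtype = "float64",
                            order = "row-major"),
                       paste0(bin, ".json"), auto_unbox = TRUE)
  tab <- cbind(fs$positions, label = as.character(fs$labels),
               rpe_depth = fs$rpe_depths)
  utils::write.csv(tab, paste0(stem, ".samples.csv"), row.names = FALSE)
  invisible(stem)
}
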