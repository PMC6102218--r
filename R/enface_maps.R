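#' Compute an en face signature-probability map
#'
#' Runs the trained classifier over the requested A-scans of one eye and
#' arranges the three sigmoid outputs on the en face plane, one pixel per
#' A-scan. Positions not evaluated are masked (`NA`).
#'
#' @param model Trained `mlp_model`.
#' @param norm The frozen training [fit_normalizer()].
#' @param vol An [oct_volume()].
#' @param positions `"all"` to classify every A-scan, `"labeled"` to restrict
#'   to labeled (non-UNLABELED) cells of `label_map`.
#' @param label_map Required when `positions = "labeled"`.
#' @param preprocess,params Pipeline parameters.
#' @return An object of class `probability_map`: list `p` of three
#'   `(n_bscans, n_ascans)` matrices (`PED`, `RD`, `NEITHER`), logical
#'   `mask` of evaluated positions, and `eye_id`.
#' @export
probability_map <- function(model, norm, vol, positions = c("all", "labeled"),
                            label_map = NULL,
                            preprocess = preprocess_params(),
                            params = feature_params()) {
  stopifnot(inherits(model, "mlp_model"), inherits(vol, "oct_volume"))
  positions <- match.arg(positions)
  if (feature_length(params) != model$config$layer_sizes[1])
    abort_validation("feature length (%d) does not match the network input (%d)",
                     feature_length(params), model$config$layer_sizes[1])
  if (positions == "labeled") {
    if (is.null(label_map)) abort_validation("positions = 'labeled' needs a label_map")
    if (!identical(as.integer(dim(label_map$labels)), c(vol$n_bscans, vol$n_ascans)))
      abort_validation("label map shape does not match the volume en face plane")
    sel <- which(label_map$labels != "UNLABELED", arr.ind = TRUE)
  } else {
    sel <- as.matrix(expand.grid(row = seq_len(vol$n_bscans),
                                 col = seq_len(vol$n_ascans)))
  }
  pp <- preprocess_volume(vol, preprocess)
  rpe_map <- locate_rpe_volume(pp, params)
  mask <- matrix(FALSE, vol$n_bscans, vol$n_ascans)
  maps <- lapply(signature_classes(), function(k)
    matrix(NA_real_, vol$n_bscans, vol$n_ascans))
  names(maps) <- signature_classes()
  if (nrow(sel) > 0) {
    sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
    ex <- extract_feature_rows(pp, rpe_map, sel, params)
    proba <- predict_proba(model, apply_normalizer(norm, ex$features))
    lin <- sel[, 1] + (sel[, 2] - 1) * vol$n_bscans
    for (k in signature_classes()) maps[[k]][lin] <- proba[, k]
    mask[lin] <- TRUE
  }
  structure(list(p = maps, mask = mask, eye_id = vol$eye_id),
            class = "probability_map")
}

col2rgb01 <- function(col) as.vector(grDevices::col2rgb(col)) / 255

# Boundary pixels of the labeled regions of a map: any labeled cell with at
# least one four-neighbor carrying a different label.
label_boundaries <- function(labels) {
  n <- nrow(labels); m <- ncol(labels)
  diff_any <- matrix(FALSE, n, m)
  if (n > 1) {
    d <- labels[-1, , drop = FALSE] != labels[-n, , drop = FALSE]
    diff_any[-n, ] <- diff_any[-n, , drop = FALSE] | d
    diff_any[-1, ] <- diff_any[-1, , drop = FALSE] | d
  }
  if (m > 1) {
    d <- labels[, -1, drop = FALSE] != labels[, -m, drop = FALSE]
    diff_any[, -m] <- diff_any[, -m, drop = FALSE] | d
    diff_any[, -1] <- diff_any[, -1, drop = FALSE] | d
  }
  diff_any
}

#' Overlay human-label boundaries on a probability heat map
#'
#' Renders one class's probability map through a fixed colormap and draws the
#' boundaries of the human-labeled PED and RD regions on top (default: green
#' for PED, yellow for RD, as in standard signature-map figures). A boundary
#' pixel is one with at least one four-neighbor of a different label.
#'
#' @param pmap A [probability_map()].
#' @param human A [signature_label_map()] with matching shape.
#' @param class Which probability plane to render (default `"PED"`).
#' @param colors Named list of boundary colors for `PED` and `RD`.
#' @param colormap Vector of colors for probabilities 0..1 (default inferno).
#' @param background Color for masked pixels.
#' @return RGB array `(n_bscans, n_ascans, 3)` in `[0, 1]`.
#' @export
overlay_boundaries <- function(pmap, human, class = "PED",
                               colors = list(PED = "green", RD = "yellow"),
                               colormap = grDevices::hcl.colors(256, "Inferno"),
                               background = "gray20") {
  stopifnot(inherits(pmap, "probability_map"), inherits(human, "signature_label_map"))
  plane <- pmap$p[[class]]
  if (!identical(dim(human$labels), dim(plane)))
    abort_validation("probability map and human map shapes disagree")
  img <- render_heatmap(plane, pmap$mask, colormap, background)
  bnd <- label_boundaries(human$labels)
  for (k in c("PED", "RD")) {
    sel <- bnd & human$labels == k
    rgbk <- col2rgb01(colors[[k]])
    for (ch in 1:3) {
      plane_ch <- img[, , ch]
      plane_ch[sel] <- rgbk[ch]
      img[, , ch] <- plane_ch
    }
  }
  img
}

render_heatmap <- function(plane, mask, colormap, background) {
  n <- nrow(plane); m <- ncol(plane)
  img <- array(0, c(n, m, 3))
  bg <- col2rgb01(background)
  idx <- pmin(pmax(floor(plane * length(colormap)) + 1, 1), length(colormap))
  rgbs <- grDevices::col2rgb(colormap) / 255
  for (ch in 1:3) {
    v <- matrix(bg[ch], n, m)
    v[mask] <- rgbs[ch, idx[mask]]
    img[, , ch] <- v
  }
  img
}

#' Colorize a B-scan by per-A-scan predicted class
#'
#' Tints each A-scan column of a grayscale B-scan by its predicted class
#' (multiplicative tint, so a white/neutral color leaves the image
#' unchanged), or draws a colored class strip along the anterior edge.
#'
#' @param bscan Numeric matrix `(n_ascans, depth)` in `[0, 1]`, i.e. one page
#'   of `vol$intensities[b, , ]`.
#' @param predictions Factor/character of length `n_ascans` over
#'   [signature_classes()].
#' @param colors Named list of tint colors per class.
#' @param mode `"tint"` (default) or `"strip"`.
#' @param strip_px Strip thickness in depth pixels for `mode = "strip"`.
#' @return RGB array `(n_ascans, depth, 3)`.
#' @export
colorize_bscan <- function(bscan, predictions,
                           colors = list(PED = "green", RD = "yellow", NEITHER = "white"),
                           mode = c("tint", "strip"), strip_px = 8) {
  check_probability_image(bscan, "bscan")
  mode <- match.arg(mode)
  f <- factor(as.character(predictions), levels = signature_classes())
  if (length(f) != nrow(bscan) || anyNA(f))
    abort_validation("predictions must give one class per A-scan row of the B-scan")
  rgbs <- vapply(signature_classes(), function(k) col2rgb01(colors[[k]]), numeric(3))
  img <- array(0, c(dim(bscan), 3))
  for (ch in 1:3) {
    w <- rgbs[ch, as.integer(f)]
    img[, , ch] <- if (mode == "tint") bscan * w else bscan
  }
  if (mode == "strip") {
    cols <- seq_len(min(strip_px, ncol(bscan)))
    for (ch in 1:3) img[, cols, ch] <- matrix(rgbs[ch, as.integer(f)],
                                              nrow(bscan), length(cols))
  }
  img
}

#' Write an RGB image array as PNG
#'
#' @param img Array `(h, w, 3)` in `[0, 1]`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
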