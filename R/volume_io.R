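#' Signature class levels
#'
#' The classifier distinguishes three signature classes: pigment epithelial
#' detachment (`"PED"`), serous retinal detachment (`"RD"`), and `"NEITHER"`.
#' Label maps additionally carry `"UNLABELED"` for equivocal A-scans that the
#' human grader declined to label; these are excluded from training and from
#' performance metrics.
#'
#' @return `signature_classes()` returns the three trainable classes, in the
#'   fixed order used by every confusion matrix and probability vector;
#'   `signature_levels()` additionally includes `"UNLABELED"`.
#' @export
signature_classes <- function() c("PED", "RD", "NEITHER")

#' @rdname signature_classes
#' @export
signature_levels <- function() c("PED", "RD", "NEITHER", "UNLABELED")

#' OCT volume container
#'
#' An `oct_volume` holds one eye's volumetric scan as a 3-D array indexed
#' `(bscan, ascan, depth)` with intensities proportional to log-scaled
#' reflectivity, stored in `[0, 1]`. Depth index increases posteriorly
#' (anterior structures have smaller depth indices). All indexing is 1-based.
#'
#' @param intensities 3-D numeric array `(n_bscans, n_ascans, depth)`, finite,
#'   in `[0, 1]`.
#' @param eye_id Character scalar identifying the eye.
#' @param lateral_extent_mm Numeric pair, the scanned area in mm (default
#'   6 x 6, the macular cube protocol).
#' @return An object of class `oct_volume` with fields `intensities`,
#'   `eye_id`, `lateral_extent_mm`, `n_bscans`, `n_ascans`, `depth`.
#' @export
oct_volume <- function(intensities, eye_id = "eye", lateral_extent_mm = c(6, 6)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3)
    abort_validation("intensities must be a 3-D array (bscan, ascan, depth)")
  d <- dim(intensities)
  if (any(d <= 0)) abort_validation("all volume dimensions must be positive")
  if (any(!is.finite(intensities)))
    abort_validation("volume intensities must all be finite")
  rng <- range(intensities)
  if (rng[1] < 0 || rng[2] > 1)
    abort_validation("volume intensities must lie in [0, 1]; observed range [%g, %g]",
                     rng[1], rng[2])
  structure(
    list(intensities = intensities,
         eye_id = as.character(eye_id)[1],
         lateral_extent_mm = as.numeric(lateral_extent_mm)[1:2],
         n_bscans = d[1], n_ascans = d[2], depth = d[3]),
    class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf("<oct_volume> eye '%s': %d B-scans x %d A-scans x %d depth px, range [%.3f, %.3f]\n",
              x$eye_id, x$n_bscans, x$n_ascans, x$depth,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' En face signature label map
#'
#' Per-A-scan class labels on the en face plane of one eye: a character matrix
#' of shape `(n_bscans, n_ascans)` over [signature_levels()].
#'
#' @param labels Character matrix with entries in
#'   `c("PED", "RD", "NEITHER", "UNLABELED")`.
#' @param eye_id Character scalar identifying the eye.
#' @return An object of class `signature_label_map`.
#' @export
signature_label_map <- function(labels, eye_id = "eye") {
  if (!is.matrix(labels) || !is.character(labels))
    abort_validation("labels must be a character matrix")
  bad <- setdiff(unique(as.vector(labels)), signature_levels())
  if (length(bad))
    abort_validation("unknown label value(s): %s", paste(bad, collapse = ", "))
  structure(list(labels = labels, eye_id = as.character(eye_id)[1]),
            class = "signature_label_map")
}

#' @export
print.signature_label_map <- function(x, ...) {
  cnt <- label_counts(x)
  cat(sprintf("<signature_label_map> eye '%s': %d x %d (%s)\n",
              x$eye_id, nrow(x$labels), ncol(x$labels),
              paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", ")))
  invisible(x)
}

#' Count labels per class in a label map
#'
#' @param map A [signature_label_map()].
#' @return Named integer vector over [signature_levels()].
#' @export
label_counts <- function(map) {
  stopifnot(inherits(map, "signature_label_map"))
  tab <- table(factor(map$labels, levels = signature_levels()))
  out <- as.integer(tab)
  names(out) <- signature_levels()
  out
}

tiff_extension <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

raw_sidecar_path <- function(path) paste0(path, ".json")

#' Read an OCT volume from disk
#'
#' Supported formats: a multi-page TIFF stack with one page per B-scan, each
#' page a `(depth x n_ascans)` image; or a raw binary array (extension `.raw`
#' or `.bin`) with a JSON sidecar `<path>.json` declaring
#' `{"shape": [n_bscans, n_ascans, depth], "dtype": ...}`. Integer pixel types
#' are rescaled to `[0, 1]` by the dtype maximum; float inputs outside
#' `[0, 1]` are clipped with a warning.
#'
#' @param path File to read.
#' @param geometry Optional expected shape `c(n_bscans, n_ascans, depth)`; a
#'   mismatch raises a validation error.
#' @param eye_id Eye identifier attached to the result (default: file name).
#' @return An [oct_volume()].
#' @export
read_volume <- function(path, geometry = NULL, eye_id = NULL) {
  if (!file.exists(path)) abort_io("cannot read volume: no such file '%s'", path)
  if (is.null(eye_id)) eye_id <- tools::file_path_sans_ext(basename(path))
  if (tiff_extension(path)) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) abort_io("failed to read TIFF '%s': %s", path, conditionMessage(e)))
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1]  # tolerate gray stored with channels
      p
    })
    shapes <- vapply(pages, dim, integer(2))
    if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
      abort_format("TIFF pages of '%s' have inconsistent shapes", path)
    # page rows = depth, page cols = A-scans; stack pages along B-scans
    arr <- aperm(simplify2array(pages), c(3, 2, 1))
  } else {
    sidecar <- raw_sidecar_path(path)
    if (!file.exists(sidecar))
      abort_format("raw volume '%s' requires a JSON sidecar '%s'", path, sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$shape) || length(meta$shape) != 3)
      abort_format("sidecar '%s' must declare a length-3 'shape'", sidecar)
    shp <- as.integer(meta$shape)
    n <- prod(shp)
    dtype <- if (is.null(meta$dtype)) "float64" else meta$dtype
    con <- file(path, "rb"); on.exit(close(con))
    vals <- switch(dtype,
      float64 = readBin(con, "double", n = n, size = 8),
      float32 = readBin(con, "double", n = n, size = 4),
      uint8   = readBin(con, "integer", n = n, size = 1, signed = FALSE) / 255,
      uint16  = readBin(con, "integer", n = n, size = 2, signed = FALSE) / 65535,
      abort_format("unsupported dtype '%s' in sidecar '%s'", dtype, sidecar))
    if (length(vals) != n)
      abort_format("raw volume '%s' holds %d values, sidecar declares %d", path, length(vals), n)
    # stored depth-fastest: (depth, ascan, bscan), matching the TIFF layout
    arr <- aperm(array(vals, dim = rev(shp)), c(3, 2, 1))
  }
  rng <- range(arr)
  if (rng[1] < 0 || rng[2] > 1) {
    warning("volume '", path, "' has values outside [0, 1]; clipping", call. = FALSE)
    arr[arr < 0] <- 0
    arr[arr > 1] <- 1
  }
  if (!is.null(geometry)) {
    geometry <- as.integer(geometry)
    if (!identical(dim(arr), geometry))
      abort_validation("volume shape (%s) does not match declared geometry (%s)",
                       paste(dim(arr), collapse = ","), paste(geometry, collapse = ","))
  }
  oct_volume(arr, eye_id = eye_id)
}

#' Write an OCT volume to disk
#'
#' TIFF output (`.tif`/`.tiff`) stores one 32-bit float page per B-scan, so a
#' round trip is exact at single precision. Raw output (any other extension)
#' stores float64 with a JSON sidecar and round-trips bitwise.
#'
#' @param vol An [oct_volume()].
#' @param path Destination path; format chosen by extension.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  ok <- tryCatch({
    if (tiff_extension(path)) {
      pages <- lapply(seq_len(vol$n_bscans), function(b) t(vol$intensities[b, , ]))
      tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
    } else {
      con <- file(path, "wb")
      writeBin(as.vector(aperm(vol$intensities, c(3, 2, 1))), con, size = 8)
      close(con)
      jsonlite::write_json(
        list(shape = c(vol$n_bscans, vol$n_ascans, vol$depth), dtype = "float64"),
        raw_sidecar_path(path), auto_unbox = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok) && !is.logical(ok))
    abort_io("failed to write volume to '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

read_binary_mask <- function(path) {
  if (!file.exists(path)) abort_io("cannot read mask: no such file '%s'", path)
  img <- if (tiff_extension(path)) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  u <- unique(as.vector(img))
  if (!all(abs(u) < 1e-6 | abs(u - 1) < 1e-6))
    abort_format("mask '%s' is not binary (0/255 in 8-bit terms)", path)
  img > 0.5
}

#' Read en face label masks into a signature label map
#'
#' Each mask is a binary 8-bit image (0 = unset, 255 = set) of shape
#' `(n_bscans, n_ascans)`, one per class, as painted by a human grader
#' scrolling through the en face stack. Cells set in no mask become
#' `UNLABELED` (equivocal). Cells set in both the PED and RD masks resolve to
#' `PED` (the distinguishing stratum); any overlap involving the NEITHER mask
#' is rejected.
#'
#' @param path_ped,path_rd,path_neither Mask image paths (PNG or TIFF).
#' @param eye_id Eye identifier.
#' @return A [signature_label_map()].
#' @export
read_label_masks <- function(path_ped, path_rd, path_neither, eye_id = "eye") {
  ped <- read_binary_mask(path_ped)
  rd <- read_binary_mask(path_rd)
  nei <- read_binary_mask(path_neither)
  if (!identical(dim(ped), dim(rd)) || !identical(dim(ped), dim(nei)))
    abort_validation("label masks have mismatching shapes")
  if (any(nei & (ped | rd)))
    abort_validation("NEITHER mask overlaps a signature mask; only PED/RD may overlap")
  labels <- matrix("UNLABELED", nrow(ped), ncol(ped))
  labels[nei] <- "NEITHER"
  labels[rd] <- "RD"
  labels[ped] <- "PED"  # precedence: PED wins over RD
  signature_label_map(labels, eye_id = eye_id)
}

volume_shape <- function(v) {
  if (inherits(v, "oct_volume")) return(c(v$n_bscans, v$n_ascans, v$depth))
  if (is.numeric(v) && length(v) == 3) return(as.integer(v))
  if (is.list(v) && all(c("n_bscans", "n_ascans", "depth") %in% names(v)))
    return(as.integer(c(v$n_bscans, v$n_ascans, v$depth)))
  abort_validation("catalog entries must be oct_volume objects or length-3 shapes")
}

#' Catalog statistics for a collection of scans
#'
#' Tallies geometry and label counts over a cohort. Each volume entry may be a
#' full [oct_volume()] or just its shape `c(n_bscans, n_ascans, depth)`, so
#' study-scale totals (e.g. 24 eyes at 256 x 512 x 992) can be computed
#' without materializing the voxel data.
#'
#' @param volumes List of [oct_volume()] objects and/or length-3 shapes.
#' @param maps Optional list of [signature_label_map()] aligned with `volumes`.
#' @return An object of class `scan_catalog` with fields `n_eyes`,
#'   `per_eye_shapes` (matrix with one row per eye), `total_ascans`,
#'   `per_class_label_counts`.
#' @export
catalog <- function(volumes, maps = NULL) {
  if (!is.null(maps) && length(maps) != length(volumes))
    abort_validation("volumes (%d) and maps (%d) differ in length", length(volumes), length(maps))
  shapes <- if (length(volumes)) t(vapply(volumes, volume_shape, integer(3)))
            else matrix(integer(0), 0, 3)
  colnames(shapes) <- c("n_bscans", "n_ascans", "depth")
  counts <- stats::setNames(integer(4), signature_levels())
  if (!is.null(maps)) {
    for (i in seq_along(maps)) {
      m <- maps[[i]]
      if (!identical(as.integer(dim(m$labels)), as.integer(shapes[i, 1:2])))
        abort_validation("map %d en face shape does not match its volume", i)
      counts <- counts + label_counts(m)
    }
  }
  structure(
    list(n_eyes = nrow(shapes),
         per_eye_shapes = shapes,
         total_ascans = sum(as.numeric(shapes[, 1]) * as.numeric(shapes[, 2])),
         per_class_label_counts = counts),
    class = "scan_catalog")
}

#' @export
print.scan_catalog <- function(x, ...) {
  cat(sprintf("<scan_catalog> %d eye(s), %s A-scans total\n", x$n_eyes,
              format(x$total_ascans, big.mark = ",")))
  if (any(x$per_class_label_counts > 0))
    cat("  labels:", paste(sprintf("%s=%d", names(x$per_class_label_counts),
                                   x$per_class_label_counts), collapse = ", "), "\n")
  invisible(x)
}

#' Write a scan catalog as JSON
#'
#' @param cat_obj A `scan_catalog`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_catalog <- function(cat_obj, path) {
  stopifnot(inherits(cat_obj, "scan_catalog"))
  jsonlite::write_json(
    list(n_eyes = cat_obj$n_eyes,
         per_eye_shapes = apply(cat_obj$per_eye_shapes, 1, as.integer, simplify = FALSE),
         total_ascans = cat_obj$total_ascans,
         per_class_label_counts = as.list(cat_obj$per_class_label_counts)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' En face re-slicing and projection
#'
#' `enface_slice` extracts the coronal plane at one depth; `enface_projection`
#' reduces a depth range with `mean` or `max`. Both return a
#' `(n_bscans, n_ascans)` matrix, one pixel per A-scan.
#'
#' @param vol An [oct_volume()].
#' @param depth_index Depth index in `[1, depth]`.
#' @return A numeric matrix `(n_bscans, n_ascans)`.
#' @export
enface_slice <- function(vol, depth_index) {
  stopifnot(inherits(vol, "oct_volume"))
  if (!is_count(depth_index) || depth_index > vol$depth)
    abort_validation("depth_index must lie in [1, %d]", vol$depth)
  vol$intensities[, , depth_index]
}

#' @rdname enface_slice
#' @param depth_range Inclusive depth range `c(lo, hi)` (default: full depth).
#' @param reducer `"mean"` or `"max"`, applied along depth only.
#' @export
enface_projection <- function(vol, depth_range = c(1, vol$depth),
                              reducer = c("mean", "max")) {
  stopifnot(inherits(vol, "oct_volume"))
  reducer <- match.arg(reducer)
  lo <- depth_range[1]; hi <- depth_range[2]
  if (!is_count(lo) || !is_count(hi) || lo > hi || hi > vol$depth)
    abort_validation("depth_range must satisfy 1 <= lo <= hi <= %d", vol$depth)
  sub <- vol$intensities[, , lo:hi, drop = FALSE]
  if (reducer == "mean") {
    rowMeans(sub, dims = 2)
  } else {
    out <- sub[, , 1]
    for (k in seq_len(dim(sub)[3])[-1]) out <- pmax(out, sub[, , k])
    out
  }
}
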