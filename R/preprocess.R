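#' Preprocessing parameters
#'
#' B-scans are denoised with a square median filter and then
#' contrast-normalized with contrast-limited adaptive histogram equalization
#' (CLAHE), independently per B-scan. The operators are fixed; their
#' parameters are not dictated by the method and default to field-standard
#' values.
#'
#' @param median_kernel Odd side length of the median window (default 3,
#'   i.e. 3 x 3).
#' @param clahe_clip_limit Histogram clip limit as a fraction on the `[0, 1]`
#'   intensity scale (default 0.01); larger values allow more contrast
#'   amplification.
#' @param clahe_tiles Tile grid `c(rows, cols)` for CLAHE (default 8 x 8).
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(median_kernel = 3, clahe_clip_limit = 0.01,
                              clahe_tiles = c(8, 8)) {
  if (!is_count(median_kernel) || median_kernel %% 2 != 1)
    abort_validation("median_kernel must be an odd integer >= 1")
  if (!is.numeric(clahe_clip_limit) || clahe_clip_limit <= 0)
    abort_validation("clahe_clip_limit must be > 0")
  if (length(clahe_tiles) != 2 || any(clahe_tiles < 1))
    abort_validation("clahe_tiles must be two counts >= 1")
  structure(list(median_kernel = as.integer(median_kernel),
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tiles = as.integer(clahe_tiles)),
            class = "preprocess_params")
}

# Edge-inclusive mirror indices for reflection padding.
reflect_index <- function(n, r) {
  if (r == 0) return(seq_len(n))
  c(pmin(r:1, n), seq_len(n), pmax(n - seq_len(r) + 1, 1))
}

# Median of nine vectorized inputs via Paeth's 19-exchange sorting network;
# used for the fast path of the default 3 x 3 kernel.
median9 <- function(p) {
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  p[[5]]
}

#' Median-filter a B-scan
#'
#' Replaces each pixel with the median of its `kernel x kernel` neighborhood.
#' Borders are handled by edge-inclusive reflection padding, so the output has
#' the same shape as the input and never leaves the input's value range.
#'
#' @param bscan Numeric matrix (any orientation).
#' @param kernel Odd window side length (default 3).
#' @return Filtered matrix, same shape.
#' @export
median_filter_bscan <- function(bscan, kernel = 3) {
  check_probability_image(bscan, "bscan")
  if (!is_count(kernel) || kernel %% 2 != 1)
    abort_validation("kernel must be an odd integer >= 1")
  if (kernel == 1) return(bscan)
  r <- (kernel - 1L) / 2L
  pad <- bscan[reflect_index(nrow(bscan), r), reflect_index(ncol(bscan), r)]
  n <- nrow(bscan); m <- ncol(bscan)
  if (kernel == 3) {
    shifts <- vector("list", 9)
    k <- 0
    for (dj in 0:2) for (di in 0:2) {
      k <- k + 1
      shifts[[k]] <- pad[di + seq_len(n), dj + seq_len(m)]
    }
    return(matrix(median9(shifts), n, m))
  }
  nb <- matrix(0, n * m, kernel * kernel)
  k <- 0
  for (dj in seq_len(kernel) - 1) for (di in seq_len(kernel) - 1) {
    k <- k + 1
    nb[, k] <- pad[di + seq_len(n), dj + seq_len(m)]
  }
  matrix(apply(nb, 1, stats::median), n, m)
}

#' Contrast-limited adaptive histogram equalization of a B-scan
#'
#' Tile-based histogram equalization with clipping (Zuiderveld's algorithm,
#' via \pkg{EBImage}). The clip limit is given as a fraction of the `[0, 1]`
#' intensity scale and converted to the bin-relative limit the algorithm
#' uses internally (256 bins). Images whose sides are not multiples of the
#' tile grid are edge-padded for the transform and cropped back. Constant
#' images are returned unchanged (there is no contrast to redistribute).
#'
#' @param bscan Numeric matrix with values in `[0, 1]`.
#' @param clip_limit Positive clip limit fraction (default 0.01).
#' @param tiles Tile grid `c(rows, cols)` (default 8 x 8).
#' @return Equalized matrix in `[0, 1]`, same shape.
#' @export
clahe_bscan <- function(bscan, clip_limit = 0.01, tiles = c(8, 8)) {
  check_probability_image(bscan, "bscan")
  if (!is.numeric(clip_limit) || clip_limit <= 0)
    abort_validation("clip_limit must be > 0")
  if (min(bscan) < 0 || max(bscan) > 1)
    abort_validation("bscan values must lie in [0, 1]")
  if (max(bscan) == min(bscan)) return(bscan)
  n <- nrow(bscan); m <- ncol(bscan)
  nx <- as.integer(tiles[1]); ny <- as.integer(tiles[2])
  np <- ceiling(n / nx) * nx
  mp <- ceiling(m / ny) * ny
  img <- bscan[pmin(seq_len(np), n), pmin(seq_len(mp), m)]
  out <- EBImage::clahe(img, nx = nx, ny = ny, bins = 256,
                        limit = clip_limit * 256, keep.range = FALSE)
  out <- out[seq_len(n), seq_len(m)]
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Preprocess a whole volume
#'
#' Applies the median filter and then CLAHE to every B-scan independently
#' (2-D transforms are applied at the B-scan level); geometry is unchanged.
#'
#' @param vol An [oct_volume()].
#' @param params A [preprocess_params()].
#' @return A preprocessed [oct_volume()].
#' @export
preprocess_volume <- function(vol, params = preprocess_params()) {
  stopifnot(inherits(vol, "oct_volume"), inherits(params, "preprocess_params"))
  out <- vol$intensities
  for (b in seq_len(vol$n_bscans)) {
    page <- median_filter_bscan(vol$intensities[b, , ], params$median_kernel)
    out[b, , ] <- clahe_bscan(page, params$clahe_clip_limit, params$clahe_tiles)
  }
  oct_volume(out, eye_id = vol$eye_id, lateral_extent_mm = vol$lateral_extent_mm)
}
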