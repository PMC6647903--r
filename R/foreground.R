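#' Construct a TMA spot image
#'
#' A spot image is an RGB raster of one tissue-microarray core with a known
#' physical pixel size. Channel values live in `[0, 1]`.
#'
#' @param pixels numeric `H x W x 3` array with values in `[0, 1]`.
#' @param pixel_size_um physical side length of one pixel in micrometres.
#'   The default 0.22 matches a 20x whole-slide scan.
#' @return An object of class `spot_image`.
#' @export
spot_image <- function(pixels, pixel_size_um = 0.22) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one pixel")
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    stop("channel values must be finite and in [0, 1]")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive scalar")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "spot_image")
}

#' @export
print.spot_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<spot_image> %d x %d px, %.2f um/px\n", d[1], d[2],
              x$pixel_size_um))
  invisible(x)
}

#' Read / write spot images as PNG
#'
#' @param path file path.
#' @param pixel_size_um physical pixel size to attach on read.
#' @return `read_spot_png()` returns a [spot_image()];
#'   `write_spot_png()` returns `path` invisibly.
#' @export
read_spot_png <- function(path, pixel_size_um = 0.22) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  spot_image(px, pixel_size_um)
}

#' @param image a [spot_image()].
#' @rdname read_spot_png
#' @export
write_spot_png <- function(image, path) {
  stopifnot(inherits(image, "spot_image"))
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' Read a spot raster (PNG or TIFF) by file extension
#'
#' @rdname read_spot_png
#' @export
read_spot_image <- function(path, pixel_size_um = 0.22) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF rasters requires the 'tiff' package")
    px <- tiff::readTIFF(path)
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
    if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
    return(spot_image(px, pixel_size_um))
  }
  read_spot_png(path, pixel_size_um)
}

#' Average colour channels to grayscale
#'
#' Per-pixel unweighted mean of the three channels (no luma weighting).
#'
#' @param image a [spot_image()] or an `H x W x 3` array.
#' @return numeric `H x W` matrix in `[0, 1]`.
#' @export
to_grayscale <- function(image) {
  px <- if (inherits(image, "spot_image")) image$pixels else image
  (px[, , 1] + px[, , 2] + px[, , 3]) / 3
}

# Normalised 1-D Gaussian kernel truncated at `radius` taps either side.
gaussian_kernel_1d <- function(radius, sigma) {
  t <- seq.int(-radius, radius)
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of a grayscale raster
#'
#' Convolution with a normalised 2-D Gaussian truncated at `radius_px`
#' (so a radius of 15 gives a 31 x 31 support) with standard deviation
#' `sigma` (default `radius_px / 3`, the usual three-sigma truncation).
#' Borders are handled by edge replication; the kernel sums to one, so
#' constant images are left unchanged.
#'
#' @param gray numeric matrix.
#' @param radius_px truncation radius in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @return smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(gray, radius_px = 15, sigma = radius_px / 3) {
  stopifnot(is.matrix(gray), radius_px >= 1)
  k <- gaussian_kernel_1d(radius_px, sigma)
  sep_filter2_cpp(gray, k, k)
}

#' Logarithmic intensity transform of a smoothed spot image
#'
#' Maps a smoothed grayscale image `I_g` to
#' `I_t = (ln(1 - I_g) + 2e) / (2e)` with `e` Euler's number. `I_g` is
#' first clamped to at most `1 - exp(-2e)` so the logarithm stays finite
#' and `I_t` lands in `[0, 1]`: pure white maps to 0 and black to 1. The
#' transform is strictly decreasing, so dark (tissue) pixels come out
#' high and bright background comes out low.
#'
#' @param i_g numeric matrix with values in `[0, 1]`.
#' @return matrix `I_t` with values in `[0, 1]`.
#' @export
transform_intensity <- function(i_g) {
  if (any(i_g < 0 | i_g > 1)) stop("`i_g` values must be in [0, 1]")
  two_e <- 2 * exp(1)
  clamped <- pmin(i_g, 1 - exp(-two_e))
  it <- (log(1 - clamped) + two_e) / two_e
  if (is.matrix(i_g)) dim(it) <- dim(i_g)
  it
}

#' Otsu thresholding
#'
#' Picks the threshold maximising the between-class variance over a
#' 256-bin histogram spanning the data range; ties are broken toward the
#' lower threshold. Pixels strictly above the threshold are foreground.
#' A constant image has no separable classes: an empty mask is returned
#' with a warning.
#'
#' @param x numeric matrix of finite values.
#' @param n_bins histogram resolution.
#' @return logical matrix with attribute `"threshold"`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  lo <- min(x); hi <- max(x)
  if (hi <= lo) {
    warning("constant image: Otsu threshold undefined, returning empty mask")
    out <- matrix(FALSE, nrow(x), ncol(x))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  bin <- pmin(floor((x - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  h <- tabulate(bin, nbins = n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  n <- sum(h)
  w0 <- cumsum(h) / n                       # class probability below split
  m0 <- cumsum(h * centers) / n             # unnormalised class mean
  mt <- m0[n_bins]
  # between-class variance for a split after bin t (t = 1 .. n_bins - 1)
  t_idx <- seq_len(n_bins - 1L)
  w <- w0[t_idx]
  valid <- w > 0 & w < 1
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mt * w[valid] - m0[t_idx][valid])^2 /
    (w[valid] * (1 - w[valid]))
  best <- which.max(sigma_b)                # which.max takes the first tie
  thr <- lo + best * (hi - lo) / n_bins     # upper edge of bin `best`
  out <- x > thr
  attr(out, "threshold") <- thr
  out
}

#' Remove small connected components from a binary mask
#'
#' Components (8-connected by default) with strictly fewer than
#' `min_area_px` pixels are set to background; components of exactly
#' `min_area_px` pixels are kept.
#'
#' @param mask logical matrix.
#' @param min_area_px minimum component area in pixels.
#' @param connectivity 8 (default) or 4.
#' @return logical matrix.
#' @export
remove_small_objects <- function(mask, min_area_px = 12500L,
                                 connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask), connectivity %in% c(4L, 8L))
  attributes(mask) <- list(dim = dim(mask))
  if (!any(mask)) return(mask)
  lab <- label_components_cpp(mask, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area_px)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}

#' Foreground mask container
#'
#' @param mask logical matrix.
#' @param pixel_size_um physical pixel side in micrometres.
#' @param threshold optional Otsu threshold used to produce the mask.
#' @return object of class `foreground_mask` with `area_pixels` and
#'   `area_mm2` fields.
#' @export
foreground_mask <- function(mask, pixel_size_um = 0.22, threshold = NA_real_) {
  stopifnot(is.matrix(mask), is.logical(mask), pixel_size_um > 0)
  area_px <- sum(mask)
  structure(list(
    mask = mask,
    area_pixels = area_px,
    area_mm2 = area_px * (pixel_size_um / 1000)^2,
    pixel_size_um = pixel_size_um,
    threshold = threshold
  ), class = "foreground_mask")
}

#' @export
print.foreground_mask <- function(x, ...) {
  cat(sprintf("<foreground_mask> %d x %d, %d px (%.4f mm^2)\n",
              nrow(x$mask), ncol(x$mask), x$area_pixels, x$area_mm2))
  invisible(x)
}

#' Tissue foreground segmentation of a spot image
#'
#' Composition of the segmentation stages: channel-averaged grayscale,
#' Gaussian smoothing (truncation radius 15 px), the logarithmic
#' intensity transform, Otsu thresholding (tissue is dark, hence high
#' after the transform, hence above threshold) and removal of connected
#' components below `min_object_px` pixels.
#'
#' @param image a [spot_image()].
#' @param smooth_radius_px Gaussian truncation radius.
#' @param min_object_px small-object removal threshold in pixels.
#' @return a [foreground_mask()].
#' @export
compute_foreground <- function(image, smooth_radius_px = 15,
                               min_object_px = 12500L) {
  stopifnot(inherits(image, "spot_image"))
  it <- transform_intensity(gaussian_smooth(to_grayscale(image),
                                            smooth_radius_px))
  raw <- otsu_threshold(it)
  thr <- attr(raw, "threshold")
  cleaned <- remove_small_objects(raw, min_object_px)
  foreground_mask(cleaned, image$pixel_size_um, threshold = thr)
}

#' Spot-area inclusion criterion
#'
#' A spot enters the analysis only when its tissue foreground area
#' strictly exceeds `min_area_mm2` (default 0.02 mm^2). The comparison is
#' done in square millimetres so it scales with the physical pixel size.
#'
#' @param mask a [foreground_mask()].
#' @param min_area_mm2 area threshold in mm^2.
#' @return logical scalar.
#' @export
passes_area_criterion <- function(mask, min_area_mm2 = 0.02) {
  stopifnot(inherits(mask, "foreground_mask"))
  mask$area_mm2 > min_area_mm2
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask a [foreground_mask()] or logical matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "foreground_mask")) mask$mask else mask
  png::writePNG(m * 1, path)
  invisible(path)
}
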