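#' Descriptor extractor contract
#'
#' A descriptor extractor turns an `H x W` RGB spot image into a
#' `ceil(H/stride) x ceil(W/stride)` grid of D-dimensional local
#' descriptors, one per grid cell, together with the pixel coordinates of
#' each cell centre. The mapping must be deterministic. The package ships
#' [fixture_extractor()], a fixed multi-scale filter bank; a pretrained
#' CNN can be plugged in through the same contract by supplying
#' `extract_fun` (the network is used as a frozen feature extractor, so
#' nothing here is ever trained).
#'
#' @param descriptor_dim output dimension D.
#' @param grid_stride_px pixels between adjacent grid cells.
#' @param extract_fun `function(image)` returning `list(vectors = N x D
#'   matrix, centers_px = N x 2 matrix)` in row-major grid order.
#' @param name label for printing.
#' @return object of class `descriptor_extractor`.
#' @export
descriptor_extractor <- function(descriptor_dim, grid_stride_px, extract_fun,
                                 name = "custom") {
  stopifnot(descriptor_dim >= 1, grid_stride_px >= 1,
            is.function(extract_fun))
  structure(list(descriptor_dim = as.integer(descriptor_dim),
                 grid_stride_px = as.integer(grid_stride_px),
                 extract_fun = extract_fun, name = name),
            class = "descriptor_extractor")
}

#' @export
print.descriptor_extractor <- function(x, ...) {
  cat(sprintf("<descriptor_extractor:%s> D = %d, stride = %d px\n",
              x$name, x$descriptor_dim, x$grid_stride_px))
  invisible(x)
}

# Centre pixel (row or column) of grid cell u at the given stride,
# clipped into the image for partial border cells.
grid_centers <- function(extent, stride) {
  n_cells <- ceiling(extent / stride)
  pmin((seq_len(n_cells) - 1L) * stride + ceiling(stride / 2), extent)
}

#' Deterministic filter-bank descriptor extractor
#'
#' A stand-in for a pretrained convolutional feature extractor with the
#' same interface: oriented first-derivative and Laplacian-of-Gaussian
#' filters at three scales on each colour channel, rectified (absolute
#' value) and mean-pooled over each stride-sized cell, then mapped to
#' `descriptor_dim` dimensions by a fixed seeded random projection
#' followed by half-wave rectification. All filters are band-pass, so a
#' constant image yields identical (zero-feature) descriptors on every
#' cell. The same seed always reproduces the same projection, hence the
#' same extractor.
#'
#' @param seed seed for the random projection.
#' @param descriptor_dim output dimension (512 by default, the channel
#'   count of a VGG-16 last convolutional layer this stands in for).
#' @param grid_stride_px grid stride (16 by default, the downsampling
#'   factor of that layer).
#' @param scales Gaussian scales (sigma, px) of the filter bank.
#' @return a [descriptor_extractor()].
#' @export
fixture_extractor <- function(seed = 0L, descriptor_dim = 512L,
                              grid_stride_px = 16L, scales = c(1, 1.8, 3.2)) {
  n_raw <- 3L * length(scales) * 3L      # channels x scales x filter types
  proj <- with_seed(derive_seed(seed, 1L, 4L),
                    matrix(rnorm(n_raw * descriptor_dim) / sqrt(n_raw),
                           n_raw, descriptor_dim))
  kernels <- lapply(scales, function(s) {
    r <- max(1L, ceiling(2.5 * s))
    t <- seq.int(-r, r)
    g <- exp(-t^2 / (2 * s^2)); g <- g / sum(g)
    dg <- -t / s^2 * g                    # first derivative of Gaussian
    d2g <- (t^2 / s^4 - 1 / s^2) * g      # second derivative
    d2g <- d2g - sum(d2g) * g             # exact zero DC gain (band-pass)
    list(g = g, dg = dg, d2g = d2g)
  })
  extract_fun <- function(image) {
    px <- image$pixels
    h <- dim(px)[1]; w <- dim(px)[2]
    stride <- grid_stride_px
    if (min(h, w) < stride) {
      warning("image smaller than one grid cell: returning empty set")
      return(list(vectors = matrix(0, 0, descriptor_dim),
                  centers_px = matrix(0, 0, 2)))
    }
    pooled <- vector("list", n_raw)
    idx <- 1L
    for (ch in 1:3) {
      plane <- px[, , ch]
      for (k in kernels) {
        dx <- sep_filter2_cpp(plane, k$dg, k$g)
        dy <- sep_filter2_cpp(plane, k$g, k$dg)
        lap <- sep_filter2_cpp(plane, k$d2g, k$g) +
               sep_filter2_cpp(plane, k$g, k$d2g)
        pooled[[idx]]      <- abs_pool_grid_cpp(dx, stride)
        pooled[[idx + 1L]] <- abs_pool_grid_cpp(dy, stride)
        pooled[[idx + 2L]] <- abs_pool_grid_cpp(lap, stride)
        idx <- idx + 3L
      }
    }
    raw <- vapply(pooled, as.vector, numeric(length(pooled[[1]])))
    if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
    vectors <- pmax(raw %*% proj, 0)
    rows <- grid_centers(h, stride)
    cols <- grid_centers(w, stride)
    centers <- cbind(rep(rows, times = length(cols)),
                     rep(cols, each = length(rows)))
    list(vectors = vectors, centers_px = centers)
  }
  descriptor_extractor(descriptor_dim, grid_stride_px, extract_fun,
                       name = sprintf("fixture(seed=%d)", as.integer(seed)))
}

#' Extract dense local descriptors from a spot image
#'
#' Applies the extractor over the full image grid; images of arbitrary
#' size are accepted (border cells may be partial). An image smaller than
#' one grid cell yields an empty set with a warning.
#'
#' @param image a [spot_image()].
#' @param extractor a [descriptor_extractor()].
#' @param source_id identifier stored with the set.
#' @return object of class `descriptor_set` with fields `vectors`
#'   (`N x D`), `centers_px` (`N x 2`, row/column pixel coordinates),
#'   `source_id` and `image_dim`.
#' @export
extract_descriptors <- function(image, extractor, source_id = NA_character_) {
  stopifnot(inherits(image, "spot_image"),
            inherits(extractor, "descriptor_extractor"))
  res <- extractor$extract_fun(image)
  structure(list(vectors = res$vectors, centers_px = res$centers_px,
                 source_id = source_id, image_dim = dim(image$pixels)[1:2]),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> N = %d, D = %d (%s)\n", nrow(x$vectors),
              ncol(x$vectors), x$source_id))
  invisible(x)
}

#' Keep only descriptors whose centre falls in the foreground
#'
#' Centre-in-mask rule: descriptor `i` survives iff the mask is true at
#' `centers_px[i, ]`.
#'
#' @param descriptors a `descriptor_set`.
#' @param mask a [foreground_mask()] with the same image dimensions.
#' @return filtered `descriptor_set`.
#' @export
filter_by_mask <- function(descriptors, mask) {
  stopifnot(inherits(descriptors, "descriptor_set"),
            inherits(mask, "foreground_mask"))
  if (!all(dim(mask$mask) == descriptors$image_dim))
    stop("mask dimensions do not match the descriptors' source image")
  if (nrow(descriptors$vectors) == 0L) return(descriptors)
  keep <- mask$mask[cbind(descriptors$centers_px[, 1],
                          descriptors$centers_px[, 2])]
  descriptors$vectors <- descriptors$vectors[keep, , drop = FALSE]
  descriptors$centers_px <- descriptors$centers_px[keep, , drop = FALSE]
  descriptors
}
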