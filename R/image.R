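#' Ear image container
#'
#' An `ear_image` bundles an 8-bit pixel grid with the capture metadata that
#' travels with it through the preprocessing pipeline. Pixels are stored as an
#' integer matrix (rows = height, cols = width) with values in `[0, 255]`;
#' colour captures straight off a camera may temporarily hold a
#' `height x width x 3` array until [to_grayscale()] is applied.
#'
#' @param pixels Integer matrix (grayscale) or `h x w x 3` array (colour) of
#'   intensities in `[0, 255]`.
#' @param subject_id Opaque subject identifier, or `NA`.
#' @param gender Gender label (e.g. `"F"`/`"M"`) or `NA` when unknown.
#' @param side One of `"left"`, `"right"`, `"unspecified"`.
#' @param capture_index Small integer distinguishing repeat captures.
#' @param source Optional origin identifier (file path or generated name).
#' @return An object of class `ear_image`.
#' @export
ear_image <- function(pixels, subject_id = NA_character_, gender = NA_character_,
                      side = c("unspecified", "left", "right"),
                      capture_index = 1L, source = NA_character_) {
  side <- match.arg(side)
  if (is.matrix(pixels)) {
    storage.mode(pixels) <- "integer"
  } else if (!(is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L)) {
    stop("pixels must be a matrix (grayscale) or an h x w x 3 array (colour)")
  }
  if (length(pixels) == 0L) stop("empty image")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    stop("intensities must lie in [0, 255] with no missing values")
  }
  structure(
    list(pixels = pixels, subject_id = as.character(subject_id),
         gender = as.character(gender), side = side,
         capture_index = as.integer(capture_index), source = as.character(source)),
    class = "ear_image"
  )
}

#' @export
print.ear_image <- function(x, ...) {
  d <- dim(x$pixels)
  kind <- if (length(d) == 2L) "grayscale" else "colour"
  cat(sprintf("<ear_image %dx%d %s> subject=%s gender=%s side=%s capture=%d\n",
              d[2], d[1], kind, x$subject_id, x$gender, x$side, x$capture_index))
  invisible(x)
}

#' Image width/height in pixels
#' @param image An [ear_image()].
#' @return Integer pixel count.
#' @export
image_width <- function(image) ncol(image$pixels)

#' @rdname image_width
#' @export
image_height <- function(image) nrow(image$pixels)

is_grayscale <- function(image) is.matrix(image$pixels)

# round-half-up to integer, clamped to [0, 255]
quantize8 <- function(x) {
  x <- floor(x + 0.5)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

with_pixels <- function(image, pixels) {
  out <- image
  out$pixels <- pixels
  out
}

#' Convert a capture to 8-bit grayscale
#'
#' Colour images are converted by the ITU-R BT.601 luma transform
#' `0.299 R + 0.587 G + 0.114 B`, rounded half up. Grayscale input passes
#' through unchanged, so the conversion is idempotent.
#'
#' @param image An [ear_image()] (grayscale or colour), a matrix, or an
#'   `h x w x 3` array of 8-bit intensities.
#' @return A grayscale [ear_image()] of the same dimensions.
#' @export
to_grayscale <- function(image) {
  if (!inherits(image, "ear_image")) image <- ear_image(image)
  if (is_grayscale(image)) return(image)
  px <- image$pixels
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  dim(g) <- dim(px)[1:2]
  with_pixels(image, quantize8(g))
}

#' Rectangular region of interest
#'
#' Coordinates are 0-based and half-open: the ROI covers columns
#' `[x0, x1)` and rows `[y0, y1)`, so its width is `x1 - x0` exactly.
#'
#' @param x0,y0,x1,y1 Corner coordinates in pixels.
#' @return An object of class `crop_roi`.
#' @export
crop_roi <- function(x0, y0, x1, y1) {
  v <- vapply(list(x0, y0, x1, y1), as.numeric, numeric(1))
  if (any(is.na(v)) || any(v != floor(v))) stop("ROI coordinates must be integers")
  if (!(x0 < x1 && y0 < y1)) stop("invalid ROI: need x0 < x1 and y0 < y1")
  if (x0 < 0 || y0 < 0) stop("invalid ROI: negative origin")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "crop_roi")
}

#' Crop an image to a region of interest
#'
#' The manual crop isolates the ear so that downstream keypoints come from
#' ear anatomy rather than hair, neckline or other background. An ROI that
#' extends past the image bounds is an error; nothing is silently clamped.
#'
#' @param image A grayscale [ear_image()].
#' @param roi A [crop_roi()].
#' @return The cropped [ear_image()]; metadata is preserved.
#' @export
crop_image <- function(image, roi) {
  stopifnot(inherits(image, "ear_image"), inherits(roi, "crop_roi"))
  if (!is_grayscale(image)) stop("crop expects a grayscale image")
  w <- image_width(image); h <- image_height(image)
  if (roi$x1 > w || roi$y1 > h) {
    stop(sprintf("invalid ROI: [%d,%d)x[%d,%d) outside %dx%d image",
                 roi$x0, roi$x1, roi$y0, roi$y1, w, h))
  }
  px <- image$pixels[(roi$y0 + 1L):roi$y1, (roi$x0 + 1L):roi$x1, drop = FALSE]
  with_pixels(image, px)
}

# 1-D resampling operator mapping n_in samples to n_out.
# Area averaging when shrinking (each output pixel averages the input interval
# it covers, with exact fractional overlap); bilinear at the sample centres
# when enlarging. Returns an n_out x n_in weight matrix with unit row sums.
resample_operator <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_out))
  A <- matrix(0, n_out, n_in)
  s <- n_in / n_out
  if (n_out < n_in) {
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * s; hi <- i * s
      j <- (floor(lo) + 1L):min(ceiling(hi), n_in)
      ov <- pmin(hi, j) - pmax(lo, j - 1)
      A[i, j] <- ov / s
    }
  } else {
    for (i in seq_len(n_out)) {
      src <- (i - 0.5) * s - 0.5
      src <- min(max(src, 0), n_in - 1)
      j0 <- floor(src); f <- src - j0
      A[i, j0 + 1L] <- 1 - f
      if (f > 0) A[i, j0 + 2L] <- f
    }
  }
  A
}

#' Resize an image to a fixed ear width
#'
#' Width is set to `target_width`; height is scaled to
#' `round(height * target_width / width)` (minimum 1) so proportions are
#' maintained. Shrinking uses area averaging, which doubles as the mild
#' noise-suppressing blur that makes downsized images behave like median- or
#' Gaussian-filtered ones; enlarging uses bilinear interpolation. An image
#' already at the target width is returned unchanged.
#'
#' @param image A grayscale [ear_image()].
#' @param target_width Target width in pixels (>= 1).
#' @return The resized [ear_image()].
#' @export
resize_to_width <- function(image, target_width) {
  stopifnot(inherits(image, "ear_image"), is_grayscale(image))
  target_width <- as.integer(target_width)
  if (is.na(target_width) || target_width < 1L) stop("target_width must be >= 1")
  w <- image_width(image); h <- image_height(image)
  if (w == target_width) return(image)
  target_height <- max(1L, as.integer(floor(h * target_width / w + 0.5)))
  A <- resample_operator(h, target_height)
  B <- resample_operator(w, target_width)
  px <- A %*% image$pixels %*% t(B)
  with_pixels(image, quantize8(px))
}

#' Histogram equalization
#'
#' Spreads the most frequent intensity values across the full 8-bit range,
#' sharpening edges and reducing illumination-induced variability between
#' captures. The intensity map anchors the darkest pixel at 0 and rescales
#' the cumulative distribution:
#' `v' = round((cdf(v) - 1) / (N - 1) * 255)` with `N` the pixel count.
#' The map is monotone non-decreasing over all 256 levels. A constant image
#' (the degenerate 0/0 case) is returned unchanged.
#'
#' @param image A grayscale [ear_image()].
#' @return The equalized [ear_image()].
#' @export
equalize_histogram <- function(image) {
  stopifnot(inherits(image, "ear_image"), is_grayscale(image))
  px <- image$pixels
  n <- length(px)
  counts <- tabulate(as.vector(px) + 1L, nbins = 256L)
  if (max(counts) == n) return(image)  # constant image: identity
  cdf <- cumsum(counts)
  lut <- quantize8((cdf - 1) / (n - 1) * 255)
  with_pixels(image, matrix(lut[px + 1L], nrow(px), ncol(px)))
}

#' Preprocess a capture through the fixed pipeline
#'
#' Applies the enabled stages strictly in the order grayscale -> crop ->
#' resize -> histogram equalization. The order is fixed by design: equalizing
#' before cropping lets background dominate the histogram and darkens the
#' ear, which measurably hurts identification. Disabled stages are skipped
#' without reordering.
#'
#' @param image An [ear_image()] (colour or grayscale).
#' @param config A [pipeline_config()].
#' @param roi A [crop_roi()]; required when `config$use_crop` is `TRUE`.
#' @return The preprocessed grayscale [ear_image()].
#' @export
preprocess_image <- function(image, config = pipeline_config(), roi = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- to_grayscale(image)
  if (config$use_crop) {
    if (is.null(roi)) stop("use_crop is set but no ROI was provided")
    out <- crop_image(out, roi)
  }
  if (config$use_resize) out <- resize_to_width(out, config$target_width)
  if (config$use_hist_eq) out <- equalize_histogram(out)
  out
}
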