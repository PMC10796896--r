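# Image I/O, region-of-interest masks, per-channel grayscale statistics,
# the YUV luminance transform, and exposure quality control.

# RGB -> YUV transform matrix; Y is the standard grayscale conversion.
YUV_MATRIX <- rbind(Y = c(0.2989, 0.5870, 0.1140),
                    U = c(-0.148, -0.289, 0.437),
                    V = c(0.615, -0.515, -0.100))

#' Construct an 8-bit RGB image
#'
#' @param data Integer array `height x width x 3` with values in 0--255, or
#'   a numeric array that will be checked against the same bounds.
#' @return An object of class `"rgb_image"` (an integer array).
#' @export
rgb_image <- function(data) {
  if (length(dim(data)) != 3L || dim(data)[3L] != 3L)
    stop("an RGB image needs three channels (height x width x 3)")
  if (any(data < 0) || any(data > 255)) stop("values must lie in [0, 255]")
  if (any(data != round(data))) stop("8-bit image values must be integers")
  storage.mode(data) <- "integer"
  structure(data, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d, range [%d, %d]>\n",
              dim(x)[1L], dim(x)[2L], min(x), max(x)))
  invisible(x)
}

#' Read a test-paper photograph
#'
#' Reads PNG (primary), TIFF or JPEG into an 8-bit RGB raster. An alpha
#' channel is dropped; single-channel (grayscale) files are rejected since
#' the analysis separates colour channels. JPEG decoding uses EBImage when
#' available.
#'
#' @param path Path to the image file.
#' @return An [rgb_image()].
#' @export
read_strip_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    jpg = , jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("reading JPEG requires the 'EBImage' package")
      img <- EBImage::readImage(path)
      a <- EBImage::imageData(img)
      if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
    },
    stop("unsupported image format: .", ext)
  )
  if (length(dim(arr)) < 3L)
    stop("single-channel image: the analysis requires three colour channels")
  if (dim(arr)[3L] >= 4L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(arr)[3L] != 3L)
    stop("expected a three-channel image, got ", dim(arr)[3L], " channels")
  rgb_image(round(arr * 255))
}

#' Write an image as PNG
#'
#' @param image An [rgb_image()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_strip_image <- function(image, path) {
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' Region-of-interest specifications
#'
#' Constructors for the sampling region over which channel statistics are
#' taken. `roi_default()` is the centered 257 x 693 rectangle whose pixel
#' count on the default fixture reproduces the 178,101 analysis points of
#' the reference measurement. `roi_auto` thresholds the image luminance at
#' the Otsu level, keeps the largest connected component, and centers a
#' rectangle of the configured size inside it (requires EBImage).
#'
#' @param center `(row, col)` center (1-based); `NULL` = image center.
#' @param height,width Rectangle size in pixels.
#' @param radius Disc radius in pixels.
#' @return A list of class `"roi_spec"`.
#' @export
roi_rect <- function(height, width, center = NULL) {
  stopifnot(height >= 1, width >= 1)
  structure(list(type = "rect", center = center, height = height,
                 width = width), class = "roi_spec")
}

#' @rdname roi_rect
#' @export
roi_disc <- function(radius, center = NULL) {
  stopifnot(radius > 0)
  structure(list(type = "disc", center = center, radius = radius),
            class = "roi_spec")
}

#' @rdname roi_rect
#' @export
roi_full <- function() structure(list(type = "full"), class = "roi_spec")

#' @rdname roi_rect
#' @export
roi_auto <- function(height, width) {
  stopifnot(height >= 1, width >= 1)
  structure(list(type = "auto", height = height, width = width),
            class = "roi_spec")
}

#' @rdname roi_rect
#' @export
roi_default <- function() roi_rect(257, 693)

#' Build a boolean sampling mask
#'
#' @param image_shape `(height, width)` in pixels, or an [rgb_image()].
#' @param spec A `roi_spec` (see [roi_rect()]); default [roi_default()].
#' @param image The image itself; required for `roi_auto`.
#' @return An object of class `"roi_mask"`: a logical matrix with attribute
#'   `pixel_count` equal to its number of `TRUE` cells.
#' @export
build_roi <- function(image_shape, spec = roi_default(), image = NULL) {
  if (inherits(image_shape, "rgb_image")) {
    if (is.null(image)) image <- image_shape
    image_shape <- dim(image_shape)[1:2]
  }
  h <- image_shape[1L]; w <- image_shape[2L]
  mask <- switch(spec$type,
    full = matrix(TRUE, h, w),
    rect = {
      ctr <- if (is.null(spec$center)) c((h + 1) / 2, (w + 1) / 2) else spec$center
      r0 <- round(ctr[1L] - (spec$height - 1) / 2)
      c0 <- round(ctr[2L] - (spec$width - 1) / 2)
      r1 <- r0 + spec$height - 1L; c1 <- c0 + spec$width - 1L
      if (r0 < 1 || c0 < 1 || r1 > h || c1 > w)
        stop("ROI exceeds image bounds")
      m <- matrix(FALSE, h, w); m[r0:r1, c0:c1] <- TRUE; m
    },
    disc = {
      ctr <- if (is.null(spec$center)) c((h + 1) / 2, (w + 1) / 2) else spec$center
      if (ctr[1L] - spec$radius < 1 || ctr[1L] + spec$radius > h ||
          ctr[2L] - spec$radius < 1 || ctr[2L] + spec$radius > w)
        stop("ROI exceeds image bounds")
      rr <- matrix(seq_len(h), h, w)
      cc <- matrix(seq_len(w), h, w, byrow = TRUE)
      (rr - ctr[1L])^2 + (cc - ctr[2L])^2 <= spec$radius^2
    },
    auto = {
      if (is.null(image)) stop("auto ROI requires the image itself")
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("auto ROI requires the 'EBImage' package")
      lum <- (YUV_MATRIX["Y", 1L] * image[, , 1L] +
              YUV_MATRIX["Y", 2L] * image[, , 2L] +
              YUV_MATRIX["Y", 3L] * image[, , 3L]) / 255
      thr <- EBImage::otsu(EBImage::Image(t(lum)))
      lab <- EBImage::bwlabel(EBImage::Image(t(lum > thr)))
      labs <- as.vector(EBImage::imageData(lab))
      labs <- labs[labs > 0]
      if (!length(labs)) stop("auto ROI: no foreground found")
      biggest <- as.integer(names(which.max(table(labs))))
      comp <- t(EBImage::imageData(lab)) == biggest
      rows <- range(which(rowSums(comp) > 0))
      cols <- range(which(colSums(comp) > 0))
      ctr <- c(mean(rows), mean(cols))
      build_roi(c(h, w), roi_rect(spec$height, spec$width, center = ctr))
    },
    stop("unknown ROI type: ", spec$type)
  )
  structure(mask, class = c("roi_mask", class(mask)),
            pixel_count = sum(mask))
}

#' Per-channel average grayscale over a mask
#'
#' Sums each channel over the masked pixels and divides by the sampling
#' pixel number; also reports the YUV luminance of the channel means and the
#' fraction of masked pixels saturated at 255 in any channel.
#'
#' @param image An [rgb_image()], or any numeric `h x w x 3` array in
#'   `[0, 255]` (e.g. an unquantized synthetic rendering).
#' @param mask An [build_roi()] mask of matching shape.
#' @return A list of class `"channel_stats"` with elements `mean_r`,
#'   `mean_g`, `mean_b`, `mean_y`, `n_pixels`, `clipped_fraction`.
#' @export
channel_means <- function(image, mask) {
  if (!all(dim(mask) == dim(image)[1:2]))
    stop("mask shape does not match the image")
  n <- attr(mask, "pixel_count")
  if (is.null(n)) n <- sum(mask)
  if (n == 0L) stop("empty mask: no pixels to average")
  r <- image[, , 1L][mask]; g <- image[, , 2L][mask]; b <- image[, , 3L][mask]
  means <- c(sum(r), sum(g), sum(b)) / n
  yuv <- rgb_to_yuv(means[1L], means[2L], means[3L])
  structure(list(mean_r = means[1L], mean_g = means[2L], mean_b = means[3L],
                 mean_y = yuv$y, n_pixels = n,
                 clipped_fraction = sum(r >= 255 | g >= 255 | b >= 255) / n),
            class = "channel_stats")
}

#' @export
print.channel_stats <- function(x, ...) {
  cat(sprintf(
    "channel means R %.3f  G %.3f  B %.3f  (Y %.3f); %d px, %.2f%% clipped\n",
    x$mean_r, x$mean_g, x$mean_b, x$mean_y, x$n_pixels,
    100 * x$clipped_fraction))
  invisible(x)
}

#' RGB to YUV transform
#'
#' Exact matrix product with the standard coefficients
#' (Y = 0.2989 R + 0.5870 G + 0.1140 B); Y is the grayscale value, U and V
#' the chrominance/chroma components. Total on finite real inputs; channel
#' means (real-valued) are valid inputs.
#'
#' @param r,g,b Finite numeric values (vectorized).
#' @return A list of class `"yuv_triple"` with elements `y`, `u`, `v`.
#' @details The chrominance rows sum to zero
#' (\eqn{-0.148 - 0.289 + 0.437 = 0} and \eqn{0.615 - 0.515 - 0.100 = 0}),
#' so gray inputs must map to \eqn{U = V = 0}. U and V are evaluated in the
#' algebraically equivalent factored form
#' \eqn{U = -0.148(R-B) - 0.289(G-B)}, \eqn{V = 0.615(R-G) - 0.100(B-G)}
#' so that this annihilation is exact in floating point as well.
#' @export
rgb_to_yuv <- function(r, g, b) {
  stopifnot(all(is.finite(r)), all(is.finite(g)), all(is.finite(b)))
  structure(list(y = 0.2989 * r + 0.5870 * g + 0.1140 * b,
                 u = -0.148 * (r - b) - 0.289 * (g - b),
                 v = 0.615 * (r - g) - 0.100 * (b - g)),
            class = "yuv_triple")
}

#' Exposure quality-control parameters and check
#'
#' Applied to the lowest-concentration (brightest) image of a run: the run
#' fails if that image is overexposed (too many saturated pixels, or a
#' channel mean at the ceiling) and warns if the analysis channel is far
#' from the preferred near-255 operating point.
#'
#' @param clip_tol Maximum tolerated clipped fraction (default 0.01).
#' @param high_thresh Channel-mean ceiling treated as overexposure (254).
#' @param low_thresh Underexposure warning threshold (200).
#' @return `qc_params()` returns a parameter list; `exposure_qc()` returns
#'   one of `"pass"`, `"fail_overexposed"`, `"warn_underexposed"`.
#' @export
qc_params <- function(clip_tol = 0.01, high_thresh = 254, low_thresh = 200) {
  list(clip_tol = clip_tol, high_thresh = high_thresh, low_thresh = low_thresh)
}

#' @rdname qc_params
#' @param stats A [channel_means()] result for the lowest-concentration
#'   image.
#' @param channel Analysis channel for the underexposure check.
#' @param params QC thresholds, see [qc_params()].
#' @export
exposure_qc <- function(stats, channel = "G", params = qc_params()) {
  means <- c(R = stats$mean_r, G = stats$mean_g, B = stats$mean_b,
             Y = stats$mean_y)
  if (stats$clipped_fraction > params$clip_tol ||
      any(means[c("R", "G", "B")] >= params$high_thresh))
    return("fail_overexposed")
  if (means[[channel]] < params$low_thresh) return("warn_underexposed")
  "pass"
}
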