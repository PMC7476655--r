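#' Raw color image
#'
#' An H x W x 3 array of gamma-encoded channel intensities on the common
#' 16-bit scale (0..65535), together with the bit depth of the source file.
#' 8-bit sources are rescaled by 257 on load so that both depths share one
#' metric scale.
#'
#' @param pixels H x W x 3 integer array on \[0, 65535\].
#' @param bit_depth Source bit depth, 8 or 16.
#' @param source_path Path of the decoded file, or `NA`.
#' @param linear Whether the channels are linear (`TRUE`) or sRGB
#'   gamma-encoded (`FALSE`, the state of a freshly loaded file).
#' @return An object of class `raw_color_image`.
#' @export
raw_color_image <- function(pixels, bit_depth, source_path = NA_character_,
                            linear = FALSE) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (dim(pixels)[1] < 3L || dim(pixels)[2] < 3L)
    vd_stop("image must be at least 3x3 pixels", "visdemand_format_error")
  if (!bit_depth %in% c(8L, 16L))
    vd_stop("bit_depth must be 8 or 16", "visdemand_format_error")
  if (min(pixels) < 0L || max(pixels) > 65535L)
    vd_stop("channel values must lie on [0, 65535]", "visdemand_format_error")
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         source_path = source_path, linear = isTRUE(linear)),
    class = "raw_color_image"
  )
}

#' Linear-luminance grayscale image
#'
#' The substrate of all scene metrics: a single-channel raster of integer
#' linear luminance on the 16-bit scale \[0, 65535\].
#'
#' @param pixels H x W integer matrix on \[0, 65535\].
#' @return An object of class `linear_gray_image` with fields `pixels`,
#'   `height_px`, `width_px`.
#' @export
linear_gray_image <- function(pixels) {
  stopifnot(is.matrix(pixels))
  pixels <- round(pixels)
  if (min(pixels) < 0 || max(pixels) > 65535)
    vd_stop("luminance values must lie on [0, 65535]",
            "visdemand_format_error")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, height_px = nrow(pixels), width_px = ncol(pixels)),
    class = "linear_gray_image"
  )
}

#' @export
print.linear_gray_image <- function(x, ...) {
  cat(sprintf("<linear_gray_image %d x %d, range [%d, %d]>\n",
              x$height_px, x$width_px, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.raw_color_image <- function(x, ...) {
  cat(sprintf("<raw_color_image %d x %d, %d-bit source, %s>\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$bit_depth,
              if (x$linear) "linear" else "sRGB-encoded"))
  invisible(x)
}

#' Load a snapshot frame
#'
#' Decodes a PNG or TIFF file (8- or 16-bit, grayscale or RGB) into a
#' [raw_color_image()] on the common 16-bit scale. 8-bit values are
#' multiplied by 257; grayscale files are replicated to three identical
#' channels. The container is detected from the file's magic bytes, not its
#' extension.
#'
#' @param path Path to a PNG or TIFF file.
#' @return A [raw_color_image()] (gamma-encoded; pass through
#'   [linearize_srgb()] before metric computation).
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    vd_stop(sprintf("file '%s' does not exist", path), "visdemand_io_error")
  magic <- readBin(path, "raw", 4L)
  decoded <-
    if (length(magic) >= 4L && identical(magic, PNG_SIG[1:4])) {
      read_png_raw(path)
    } else if (length(magic) >= 2L &&
               rawToChar(magic[1:2]) %in% c("II", "MM")) {
      read_tiff_raw(path)
    } else {
      vd_stop(sprintf("'%s' is neither PNG nor TIFF", path),
              "visdemand_io_error")
    }
  px <- decoded$pixels
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (decoded$bit_depth == 8L) px <- px * 257L
  raw_color_image(px, decoded$bit_depth, source_path = path, linear = FALSE)
}

# sRGB electro-optical transfer functions on the unit interval.
srgb_decode_unit <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

srgb_encode_unit <- function(v) {
  ifelse(v <= 0.0031308, v * 12.92, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Linearize sRGB channel values
#'
#' Applies the standard sRGB inverse transfer function per channel: values
#' are scaled to the unit interval, pushed through the piecewise curve
#' (linear below the 0.04045 breakpoint, power 2.4 above) and rescaled to
#' \[0, 65535\] with rounding.
#'
#' @param img A gamma-encoded [raw_color_image()].
#' @return The image with linear channels (`linear = TRUE`).
#' @export
linearize_srgb <- function(img) {
  stopifnot(inherits(img, "raw_color_image"))
  if (img$linear) return(img)
  px <- round(srgb_decode_unit(img$pixels / 65535) * 65535)
  storage.mode(px) <- "integer"
  raw_color_image(px, img$bit_depth, img$source_path, linear = TRUE)
}

#' Re-encode linear channel values to sRGB
#'
#' Inverse of [linearize_srgb()]; provided so round-trip behavior can be
#' checked and synthetic linear fixtures exported as display-referred files.
#'
#' @param img A linear [raw_color_image()].
#' @return The image with gamma-encoded channels (`linear = FALSE`).
#' @export
delinearize_srgb <- function(img) {
  stopifnot(inherits(img, "raw_color_image"))
  if (!img$linear) return(img)
  px <- round(srgb_encode_unit(img$pixels / 65535) * 65535)
  storage.mode(px) <- "integer"
  raw_color_image(px, img$bit_depth, img$source_path, linear = FALSE)
}

#' Convert a linear RGB image to linear luminance
#'
#' Weighted luminance with ITU-R BT.601 weights
#' (0.2989 R + 0.5870 G + 0.1140 B), rounded to the nearest integer on the
#' 16-bit scale. BT.709 weights can be substituted via `weights`.
#'
#' @param img A linear [raw_color_image()] (as produced by
#'   [linearize_srgb()]).
#' @param weights Length-3 RGB luminance weights; must sum to 1 within
#'   1e-3 (the conventional 4-digit BT.601 weights sum to 0.9999, so equal
#'   channels reproduce within 1 part in 10^4, not exactly).
#' @return A [linear_gray_image()].
#' @export
to_grayscale <- function(img, weights = c(0.2989, 0.5870, 0.1140)) {
  stopifnot(inherits(img, "raw_color_image"))
  if (!img$linear)
    vd_stop("to_grayscale expects a linearized image; call linearize_srgb() first",
            "visdemand_format_error")
  stopifnot(length(weights) == 3L, abs(sum(weights) - 1) < 1e-3)
  g <- weights[1] * img$pixels[, , 1] + weights[2] * img$pixels[, , 2] +
    weights[3] * img$pixels[, , 3]
  linear_gray_image(round(g))
}

#' Write a linear grayscale image as 16-bit TIFF
#'
#' @param img A [linear_gray_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_tiff <- function(img, path) {
  stopifnot(inherits(img, "linear_gray_image"))
  write_tiff_gray16(img$pixels, path)
}
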