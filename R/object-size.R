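#' Camera geometry of the recording spectacles
#'
#' Defaults match the study hardware: 1920 x 1080 frames with a 120 degree
#' horizontal field of view. The vertical field of view is derived from the
#' aspect ratio (120 * 1080/1920 = 67.5 degrees) unless given explicitly,
#' consistent with the equidistant (linear-in-pixels) angular mapping used
#' for undistorted frames.
#'
#' @param width_px,height_px Frame dimensions in pixels.
#' @param hfov_deg Horizontal field of view, degrees.
#' @param vfov_deg Vertical field of view, degrees; derived from the aspect
#'   ratio when `NULL`.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(width_px = 1920L, height_px = 1080L,
                         hfov_deg = 120, vfov_deg = NULL) {
  stopifnot(width_px >= 1L, height_px >= 1L,
            hfov_deg > 0, hfov_deg <= 180)
  if (is.null(vfov_deg)) vfov_deg <- hfov_deg * height_px / width_px
  stopifnot(vfov_deg > 0, vfov_deg <= 180)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         hfov_deg = hfov_deg, vfov_deg = vfov_deg),
    class = "camera_model"
  )
}

#' Object annotation: the pixel span of an object of interest
#'
#' @param snapshot_id Snapshot identifier.
#' @param span_h_px,span_v_px Horizontal/vertical pixel extent of the object
#'   (for written content, of a single letter); at least 1.
#' @param is_text Whether the span describes a single letter of text.
#' @return An object of class `object_annotation`.
#' @export
object_annotation <- function(snapshot_id, span_h_px, span_v_px,
                              is_text = FALSE) {
  if (span_h_px < 1 || span_v_px < 1)
    vd_stop("object spans must be at least 1 pixel", "visdemand_range_error")
  structure(
    list(snapshot_id = as.character(snapshot_id),
         span_h_px = span_h_px, span_v_px = span_v_px,
         is_text = isTRUE(is_text)),
    class = "object_annotation"
  )
}

#' Convert a pixel span to degrees of visual angle
#'
#' Linear angular mapping for undistorted frames:
#' `degrees = span_px / axis_dimension_px * axis_fov_deg`.
#'
#' @param span_px Pixel extent along the axis.
#' @param axis `"h"` (horizontal) or `"v"` (vertical).
#' @param cam A [camera_model()].
#' @return Degrees of visual angle.
#' @export
pixel_span_to_degrees <- function(span_px, axis = c("h", "v"),
                                  cam = camera_model()) {
  axis <- match.arg(axis)
  dim_px <- if (axis == "h") cam$width_px else cam$height_px
  fov <- if (axis == "h") cam$hfov_deg else cam$vfov_deg
  if (any(span_px < 1) || any(span_px > dim_px))
    vd_stop(sprintf("span must lie within [1, %d] px on axis '%s'",
                    dim_px, axis), "visdemand_range_error")
  span_px / dim_px * fov
}

#' Convert degrees of visual angle to logMAR
#'
#' `logMAR = log10(60 * degrees)`: the base-10 log of the angular size
#' expressed in arcminutes. The whole-object (or whole-letter) angle is
#' used directly, with no 1/5 letter-detail factor; this convention
#' reproduces the printed conversions it is validated against (2 degrees ->
#' 2.08 logMAR, etc.). Use `round(x, 2)` for reporting.
#'
#' @param deg Angular size in degrees; must be positive.
#' @return logMAR (unrounded).
#' @export
degrees_to_logmar <- function(deg) {
  if (any(deg <= 0))
    vd_stop("angular size must be positive", "visdemand_domain_error")
  log10(deg * 60)
}

#' Convert logMAR back to degrees
#'
#' Inverse of [degrees_to_logmar()]: `10^logmar / 60`.
#'
#' @param logmar logMAR value(s).
#' @return Degrees of visual angle.
#' @export
logmar_to_degrees <- function(logmar) {
  10^logmar / 60
}

#' Angular size of one annotated object
#'
#' Applies [pixel_span_to_degrees()] and [degrees_to_logmar()] per axis.
#'
#' @param ann An [object_annotation()].
#' @param cam A [camera_model()].
#' @return An object of class `angular_size` with fields `snapshot_id`,
#'   `deg_h`, `deg_v`, `logmar_h`, `logmar_v`.
#' @export
annotate_size <- function(ann, cam = camera_model()) {
  stopifnot(inherits(ann, "object_annotation"))
  deg_h <- pixel_span_to_degrees(ann$span_h_px, "h", cam)
  deg_v <- pixel_span_to_degrees(ann$span_v_px, "v", cam)
  structure(
    list(snapshot_id = ann$snapshot_id, deg_h = deg_h, deg_v = deg_v,
         logmar_h = degrees_to_logmar(deg_h),
         logmar_v = degrees_to_logmar(deg_v)),
    class = "angular_size"
  )
}

#' Summarize object angular sizes
#'
#' Per axis: mean, SD (sample, n-1), min and max in degrees, the same four
#' statistics converted to logMAR (the summary statistics are converted,
#' not the per-object values, matching the reporting convention the
#' conversions are validated against), and the fraction of objects strictly
#' below `threshold_deg`.
#'
#' @param sizes List of [annotate_size()] results, or a data.frame with
#'   columns `deg_h`, `deg_v`.
#' @param threshold_deg Small-object threshold in degrees (default 2).
#' @return A list with one element per axis (`h`, `v`), each containing
#'   `mean_deg`, `sd_deg`, `min_deg`, `max_deg`, the corresponding
#'   `*_logmar` values (unrounded; round to 2 decimals for reporting) and
#'   `frac_below_threshold`; plus `n` and `threshold_deg`.
#' @export
summarize_object_sizes <- function(sizes, threshold_deg = 2.0) {
  if (is.data.frame(sizes)) {
    deg <- list(h = sizes$deg_h, v = sizes$deg_v)
  } else {
    if (length(sizes) == 0L)
      vd_stop("no object sizes to summarize", "visdemand_empty_input_error")
    deg <- list(h = vapply(sizes, `[[`, numeric(1), "deg_h"),
                v = vapply(sizes, `[[`, numeric(1), "deg_v"))
  }
  if (length(deg$h) == 0L)
    vd_stop("no object sizes to summarize", "visdemand_empty_input_error")
  one_axis <- function(d) {
    s <- if (length(d) > 1L) sd(d) else 0
    stats <- c(mean = mean(d), sd = s, min = min(d), max = max(d))
    lm <- vapply(stats, function(x) if (x > 0) degrees_to_logmar(x) else NA_real_,
                 numeric(1))
    list(mean_deg = stats[["mean"]], sd_deg = stats[["sd"]],
         min_deg = stats[["min"]], max_deg = stats[["max"]],
         mean_logmar = lm[["mean"]], sd_logmar = lm[["sd"]],
         min_logmar = lm[["min"]], max_logmar = lm[["max"]],
         frac_below_threshold = mean(d < threshold_deg))
  }
  list(h = one_axis(deg$h), v = one_axis(deg$v),
       n = length(deg$h), threshold_deg = threshold_deg)
}

#' Read object annotations from CSV
#'
#' Expected columns: `snapshot_id`, `span_h_px`, `span_v_px` and optionally
#' `is_text`.
#'
#' @param path CSV path.
#' @return A list of [object_annotation()] objects.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("snapshot_id", "span_h_px", "span_v_px")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    vd_stop(sprintf("annotation CSV lacks column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "visdemand_format_error")
  if (!"is_text" %in% names(df)) df$is_text <- FALSE
  lapply(seq_len(nrow(df)), function(i)
    object_annotation(df$snapshot_id[i], df$span_h_px[i], df$span_v_px[i],
                      df$is_text[i]))
}
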