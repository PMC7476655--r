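#' Scene-metric configuration
#'
#' Bundles every tunable of the five per-image metrics. Defaults mirror the
#' conventions of the MATLAB Image Processing Toolbox routines the metric
#' definitions presuppose (256-bin tonal histograms, 9x9 entropy window with
#' symmetric padding, 3x3 range window with replicate padding, Sobel edge
#' detection with an automatic threshold).
#'
#' @param tail_fraction Fraction of pixels in each tonal tail used for the
#'   contrast extremes; `ceiling(tail_fraction * N)` pixels per tail.
#' @param entropy_bins Number of equal-width tonal bins for both global and
#'   local entropy; entropies are therefore on a 0..log2(entropy_bins) bit
#'   scale.
#' @param local_window Odd side length of the local-entropy neighborhood.
#' @param entropy_cutoff_bits Local-entropy cutoff (bits) above which a
#'   pixel counts as textured.
#' @param range_window Odd side length of the tonal-range neighborhood.
#' @param range_threshold Tonal range (16-bit counts) above which a pixel
#'   counts as high-spatial-frequency; default `round(0.1 * 2^16) = 6554`.
#' @param edge_method Edge detector; only `"sobel_auto"` is implemented:
#'   Sobel kernels scaled by 1/8 applied to the unit-scaled image with
#'   replicate padding, squared gradient magnitude g, cutoff `4 * mean(g)`,
#'   edge where `g > cutoff`, no thinning.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(tail_fraction = 0.005,
                          entropy_bins = 256L,
                          local_window = 9L,
                          entropy_cutoff_bits = 3.0,
                          range_window = 3L,
                          range_threshold = 6554L,
                          edge_method = "sobel_auto") {
  stopifnot(tail_fraction > 0, tail_fraction < 0.5,
            entropy_bins >= 2L, 65536L %% as.integer(entropy_bins) == 0L,
            local_window >= 3L, local_window %% 2L == 1L,
            range_window >= 3L, range_window %% 2L == 1L,
            range_threshold > 0L, range_threshold < 65536L,
            entropy_cutoff_bits > 0)
  edge_method <- match.arg(edge_method, "sobel_auto")
  structure(
    list(tail_fraction = tail_fraction,
         entropy_bins = as.integer(entropy_bins),
         local_window = as.integer(local_window),
         entropy_cutoff_bits = entropy_cutoff_bits,
         range_window = as.integer(range_window),
         range_threshold = as.integer(range_threshold),
         edge_method = edge_method),
    class = "metric_config"
  )
}

as_gray <- function(img) {
  if (inherits(img, "linear_gray_image")) return(img)
  if (is.matrix(img)) return(linear_gray_image(img))
  vd_stop("expected a linear_gray_image or integer matrix",
          "visdemand_format_error")
}

check_window <- function(img, window, what) {
  if (img$height_px < window || img$width_px < window)
    vd_stop(sprintf("image (%d x %d) is smaller than the %d x %d %s window",
                    img$height_px, img$width_px, window, window, what),
            "visdemand_dimension_error")
}

#' Percentile-tail contrast
#'
#' Contrast as the span of the tonal extremes relative to the full 16-bit
#' range: the mean of the `ceiling(tail_fraction * N)` brightest pixels
#' (`i_max`) minus the mean of the equally many darkest (`i_min`), divided
#' by 2^16 and expressed as a percentage. The divisor is 2^16 (not
#' 2^16 - 1), so the maximum attainable contrast is 65535/65536 * 100.
#'
#' @param img A [linear_gray_image()] (or bare integer matrix).
#' @param cfg A [metric_config()].
#' @return List with `contrast_pct`, `i_max`, `i_min`.
#' @export
compute_contrast <- function(img, cfg = metric_config()) {
  img <- as_gray(img)
  v <- sort(as.vector(img$pixels))
  n <- length(v)
  k <- ceiling(cfg$tail_fraction * n)
  i_min <- mean(v[seq_len(k)])
  i_max <- mean(v[seq.int(n - k + 1L, n)])
  list(contrast_pct = (i_max - i_min) / 65536 * 100,
       i_max = i_max, i_min = i_min)
}

# Tonal histogram over equal-width bins of the 16-bit range.
tonal_histogram <- function(pixels, bins) {
  idx <- pixels %/% (65536L %/% bins)
  tabulate(idx + 1L, nbins = bins)
}

#' Normalized global entropy
#'
#' Shannon entropy (bits) of the image's tonal histogram over
#' `entropy_bins` equal-width bins, divided by `log2(entropy_bins)` so that
#' a constant image scores 0 and a histogram uniform over all bins scores 1.
#'
#' @inheritParams compute_contrast
#' @return Normalized entropy on \[0, 1\].
#' @export
compute_global_entropy <- function(img, cfg = metric_config()) {
  img <- as_gray(img)
  counts <- tonal_histogram(img$pixels, cfg$entropy_bins)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p)) / log2(cfg$entropy_bins)
}

#' Textured-area fraction from local entropy
#'
#' Runs a per-pixel Shannon entropy filter (histogram of the
#' `local_window` x `local_window` neighborhood over `entropy_bins` tonal
#' bins, symmetric boundary padding) and reports the percentage of pixels
#' whose local entropy exceeds `entropy_cutoff_bits` (default 3 bits, a
#' cutoff separating structured texture from flat regions).
#'
#' @inheritParams compute_contrast
#' @return List with `textured_area_pct`, `pix_texture`, `pix_all`.
#' @export
compute_textured_area <- function(img, cfg = metric_config()) {
  img <- as_gray(img)
  check_window(img, cfg$local_window, "local entropy")
  ent <- entropy_filter_cpp(img$pixels, cfg$local_window, cfg$entropy_bins)
  pix_all <- length(ent)
  pix_texture <- sum(ent > cfg$entropy_cutoff_bits)
  list(textured_area_pct = 100 * pix_texture / pix_all,
       pix_texture = pix_texture, pix_all = pix_all)
}

#' High-spatial-frequency area fraction
#'
#' Runs a per-pixel tonal-range filter (max minus min over the
#' `range_window` x `range_window` neighborhood, replicate boundary
#' padding) and reports the percentage of pixels whose local range exceeds
#' `range_threshold` (default 10% of the 16-bit range, 6554 counts) — a
#' proxy for fine spatial detail.
#'
#' @inheritParams compute_contrast
#' @return List with `highfreq_area_pct`, `pix_highfreq`, `pix_all`.
#' @export
compute_highfreq_area <- function(img, cfg = metric_config()) {
  img <- as_gray(img)
  check_window(img, cfg$range_window, "range")
  rng <- range_filter_cpp(img$pixels, cfg$range_window)
  pix_all <- length(rng)
  pix_highfreq <- sum(rng > cfg$range_threshold)
  list(highfreq_area_pct = 100 * pix_highfreq / pix_all,
       pix_highfreq = pix_highfreq, pix_all = pix_all)
}

# 2-D correlation with replicate padding; kernel is a small odd matrix.
conv2_replicate <- function(m, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (di in -kr:kr) {
    ri <- pmin(pmax(seq_len(h) + di, 1L), h)
    for (dj in -kc:kc) {
      cj <- pmin(pmax(seq_len(w) + dj, 1L), w)
      k <- kernel[di + kr + 1L, dj + kc + 1L]
      if (k != 0) out <- out + k * m[ri, cj]
    }
  }
  out
}

sobel_edge_map <- function(pixels) {
  u <- pixels / 65535
  kx <- matrix(c(1, 0, -1, 2, 0, -2, 1, 0, -1), 3, 3) / 8  # d/dx (columns)
  ky <- t(kx)                                              # d/dy (rows)
  g <- conv2_replicate(u, kx)^2 + conv2_replicate(u, ky)^2
  cutoff <- 4 * mean(g)
  g > cutoff
}

#' Edge-area fraction
#'
#' Binary Sobel edge map (see [metric_config()] for the exact detector and
#' automatic threshold rule) reported as the percentage of pixels flagged
#' as edges.
#'
#' @inheritParams compute_contrast
#' @return List with `edge_area_pct`, `pix_edge`, `pix_all`.
#' @export
compute_edge_area <- function(img, cfg = metric_config()) {
  img <- as_gray(img)
  check_window(img, 3L, "edge")
  edges <- sobel_edge_map(img$pixels)
  pix_all <- length(edges)
  pix_edge <- sum(edges)
  list(edge_area_pct = 100 * pix_edge / pix_all,
       pix_edge = pix_edge, pix_all = pix_all)
}

#' All five scene metrics of one image
#'
#' Convenience wrapper running contrast, global entropy, textured area,
#' high-spatial-frequency area and edge area once, sharing the pixel count.
#'
#' @inheritParams compute_contrast
#' @return List with `metrics` (class `scene_metrics`: `contrast_pct`,
#'   `global_entropy`, `textured_area_pct`, `highfreq_area_pct`,
#'   `edge_area_pct`) and `intermediates` (class `metric_intermediates`:
#'   `i_max`, `i_min`, `pix_texture`, `pix_highfreq`, `pix_edge`,
#'   `pix_all`).
#' @export
compute_scene_metrics <- function(img, cfg = metric_config()) {
  img <- as_gray(img)
  ct <- compute_contrast(img, cfg)
  ge <- compute_global_entropy(img, cfg)
  tx <- compute_textured_area(img, cfg)
  hf <- compute_highfreq_area(img, cfg)
  ed <- compute_edge_area(img, cfg)
  metrics <- structure(
    list(contrast_pct = ct$contrast_pct, global_entropy = ge,
         textured_area_pct = tx$textured_area_pct,
         highfreq_area_pct = hf$highfreq_area_pct,
         edge_area_pct = ed$edge_area_pct),
    class = "scene_metrics"
  )
  intermediates <- structure(
    list(i_max = ct$i_max, i_min = ct$i_min,
         pix_texture = tx$pix_texture, pix_highfreq = hf$pix_highfreq,
         pix_edge = ed$pix_edge, pix_all = tx$pix_all),
    class = "metric_intermediates"
  )
  list(metrics = metrics, intermediates = intermediates)
}

#' @export
print.scene_metrics <- function(x, ...) {
  cat(sprintf(paste0("scene metrics: contrast %.1f%% | entropy %.3f | ",
                     "textured %.1f%% | high-freq %.1f%% | edges %.1f%%\n"),
              x$contrast_pct, x$global_entropy, x$textured_area_pct,
              x$highfreq_area_pct, x$edge_area_pct))
  invisible(x)
}

#' Batch scene metrics over a directory of images
#'
#' Loads every PNG/TIFF in `dir`, linearizes, converts to grayscale and
#' computes all five metrics, returning (and optionally writing) one row
#' per image with the metrics and their intermediates.
#'
#' @param dir Directory containing PNG/TIFF frames.
#' @param cfg A [metric_config()], or path to a JSON file whose fields
#'   mirror the `metric_config()` arguments.
#' @param out_csv Optional path; when given, the table is also written as
#'   CSV.
#' @return A data.frame with columns `file`, the five metrics and the six
#'   intermediates.
#' @export
batch_scene_metrics <- function(dir, cfg = metric_config(), out_csv = NULL) {
  if (is.character(cfg)) cfg <- read_metric_config(cfg)
  files <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L)
    vd_stop(sprintf("no PNG/TIFF files found in '%s'", dir),
            "visdemand_io_error")
  rows <- lapply(files, function(f) {
    gray <- to_grayscale(linearize_srgb(load_image(f)))
    res <- compute_scene_metrics(gray, cfg)
    data.frame(file = basename(f),
               as.data.frame(unclass(res$metrics)),
               as.data.frame(unclass(res$intermediates)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Read a metric configuration from JSON
#'
#' @param path JSON file whose fields mirror the [metric_config()]
#'   arguments; absent fields keep their defaults.
#' @return A [metric_config()].
#' @export
read_metric_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(metric_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    vd_stop(sprintf("unknown metric config field(s): %s",
                    paste(bad, collapse = ", ")), "visdemand_format_error")
  do.call(metric_config, vals)
}

#' Write a metric configuration to JSON
#'
#' @param cfg A [metric_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "metric_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
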