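# Minimal PNG reader: non-interlaced, 8/16-bit, grayscale (color type 0) or
# RGB (color type 2). IDAT inflation uses base R's memDecompress; scanline
# unfiltering is compiled (png_unfilter_cpp).

PNG_SIG <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))

read_png_raw <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 8L || !identical(bytes[1:8], PNG_SIG))
    vd_stop(sprintf("'%s' is not a PNG file (bad signature)", path),
            "visdemand_io_error")
  u32 <- function(off) {
    v <- readBin(bytes[(off + 1):(off + 4)], "integer", size = 4,
                 endian = "big")
    if (v < 0) vd_stop("PNG chunk length exceeds 2GB", "visdemand_format_error")
    v
  }
  pos <- 8L
  ihdr <- NULL
  idat <- list()
  seen_iend <- FALSE
  while (pos + 8L <= length(bytes)) {
    len <- u32(pos)
    typ <- rawToChar(bytes[(pos + 5L):(pos + 8L)])
    data_start <- pos + 8L
    if (data_start + len + 4L > length(bytes))
      vd_stop(sprintf("'%s': truncated PNG ('%s' chunk)", path, typ),
              "visdemand_io_error")
    if (typ == "IHDR") {
      ihdr <- list(
        width = u32(data_start), height = u32(data_start + 4L),
        bit_depth = as.integer(bytes[data_start + 9L]),
        color_type = as.integer(bytes[data_start + 10L]),
        compression = as.integer(bytes[data_start + 11L]),
        filter = as.integer(bytes[data_start + 12L]),
        interlace = as.integer(bytes[data_start + 13L])
      )
    } else if (typ == "IDAT") {
      idat[[length(idat) + 1L]] <-
        if (len > 0L) bytes[(data_start + 1L):(data_start + len)] else raw(0)
    } else if (typ == "IEND") {
      seen_iend <- TRUE
      break
    }
    pos <- data_start + len + 4L
  }
  if (is.null(ihdr) || !seen_iend || length(idat) == 0L)
    vd_stop(sprintf("'%s': truncated PNG (missing IHDR/IDAT/IEND)", path),
            "visdemand_io_error")
  if (!ihdr$color_type %in% c(0L, 2L)) {
    what <- switch(as.character(ihdr$color_type), `3` = "palette",
                   `4` = "gray+alpha", `6` = "RGBA", "unknown")
    vd_stop(sprintf("'%s': unsupported PNG color type %d (%s); need grayscale or RGB",
                    path, ihdr$color_type, what), "visdemand_format_error")
  }
  if (!ihdr$bit_depth %in% c(8L, 16L))
    vd_stop(sprintf("'%s': unsupported PNG bit depth %d", path,
                    ihdr$bit_depth), "visdemand_format_error")
  if (ihdr$interlace != 0L)
    vd_stop(sprintf("'%s': interlaced PNG not supported", path),
            "visdemand_format_error")
  stream <- do.call(c, idat)
  inflated <- tryCatch(memDecompress(stream, type = "gzip"),
                       error = function(e)
                         vd_stop(sprintf("'%s': corrupt PNG image data", path),
                                 "visdemand_io_error"))
  spp <- if (ihdr$color_type == 0L) 1L else 3L
  bytes_per_sample <- ihdr$bit_depth %/% 8L
  bpp <- spp * bytes_per_sample
  rowbytes <- ihdr$width * bpp
  if (length(inflated) < as.numeric(ihdr$height) * (rowbytes + 1L))
    vd_stop(sprintf("'%s': truncated PNG image data", path),
            "visdemand_io_error")
  data <- png_unfilter_cpp(inflated, ihdr$height, rowbytes, bpp)
  vals <- if (ihdr$bit_depth == 8L) {
    as.integer(data)
  } else {
    # PNG 16-bit samples are big-endian
    readBin(data, "integer", n = length(data) %/% 2L, size = 2,
            signed = FALSE, endian = "big")
  }
  px <- array(0L, dim = c(ihdr$height, ihdr$width, spp))
  for (s in seq_len(spp))
    px[, , s] <- matrix(vals[seq(s, length(vals), by = spp)],
                        nrow = ihdr$height, ncol = ihdr$width, byrow = TRUE)
  list(pixels = px, bit_depth = ihdr$bit_depth)
}
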