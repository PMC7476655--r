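# Minimal baseline TIFF codec.
#
# No image-I/O package ships with the target environment, so the package
# carries its own reader/writer for the narrow slice of TIFF the pipeline
# needs: single-image, uncompressed, chunky, 8- or 16-bit unsigned,
# grayscale or RGB. Anything else raises a format error naming the
# offending property.

TIFF_TAGS <- c(
  width = 256L, height = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, spp = 277L,
  rows_per_strip = 278L, strip_bytes = 279L, planar = 284L,
  sample_format = 339L
)

read_tiff_raw <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 8L)
    vd_stop(sprintf("'%s' is not a TIFF file (truncated header)", path),
            "visdemand_io_error")
  order_tag <- rawToChar(bytes[1:2])
  endian <- switch(order_tag, "II" = "little", "MM" = "big",
                   vd_stop(sprintf("'%s': unrecognized TIFF byte order", path),
                           "visdemand_format_error"))
  u16 <- function(off) readBin(bytes[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(bytes[(off + 1):(off + 4)], "integer", size = 4,
                 endian = endian)
    if (v < 0) vd_stop("TIFF offset exceeds 2GB", "visdemand_format_error")
    v
  }
  if (u16(2L) != 42L)
    vd_stop(sprintf("'%s' is not a TIFF file (bad magic)", path),
            "visdemand_io_error")
  ifd <- u32(4L)
  if (ifd + 2L > length(bytes))
    vd_stop(sprintf("'%s': truncated TIFF (IFD out of range)", path),
            "visdemand_io_error")
  n_entries <- u16(ifd)
  fields <- list()
  type_size <- c(`1` = 1L, `3` = 2L, `4` = 4L)
  for (k in seq_len(n_entries)) {
    e <- ifd + 2L + (k - 1L) * 12L
    tag <- u16(e); typ <- u16(e + 2L); cnt <- u32(e + 4L)
    if (!as.character(typ) %in% names(type_size)) next  # RATIONAL etc: skip
    sz <- type_size[[as.character(typ)]]
    off <- if (cnt * sz <= 4L) e + 8L else u32(e + 8L)
    if (off + cnt * sz > length(bytes))
      vd_stop(sprintf("'%s': truncated TIFF (tag %d data out of range)",
                      path, tag), "visdemand_io_error")
    vals <- if (typ == 1L) {
      as.integer(bytes[(off + 1L):(off + cnt)])
    } else if (typ == 3L) {
      readBin(bytes[(off + 1L):(off + cnt * sz)], "integer", n = cnt,
              size = 2, signed = FALSE, endian = endian)
    } else {
      readBin(bytes[(off + 1L):(off + cnt * sz)], "integer", n = cnt,
              size = 4, endian = endian)
    }
    fields[[as.character(tag)]] <- vals
  }
  get_tag <- function(name, default = NULL) {
    v <- fields[[as.character(TIFF_TAGS[[name]])]]
    if (is.null(v)) default else v
  }
  w <- get_tag("width"); h <- get_tag("height")
  if (is.null(w) || is.null(h))
    vd_stop(sprintf("'%s': TIFF lacks image dimensions", path),
            "visdemand_format_error")
  compression <- get_tag("compression", 1L)[1]
  if (compression != 1L)
    vd_stop(sprintf("'%s': unsupported TIFF compression %d (only uncompressed)",
                    path, compression), "visdemand_format_error")
  planar <- get_tag("planar", 1L)[1]
  if (planar != 1L)
    vd_stop(sprintf("'%s': unsupported TIFF planar configuration %d", path,
                    planar), "visdemand_format_error")
  spp <- get_tag("spp", 1L)[1]
  if (!spp %in% c(1L, 3L))
    vd_stop(sprintf("'%s': unsupported TIFF sample count %d (need 1 or 3)",
                    path, spp), "visdemand_format_error")
  bits <- get_tag("bits", 1L)
  if (length(unique(bits)) != 1L || !bits[1] %in% c(8L, 16L))
    vd_stop(sprintf("'%s': unsupported TIFF bit depth (%s)", path,
                    paste(bits, collapse = "/")), "visdemand_format_error")
  bits <- bits[1]
  fmt <- get_tag("sample_format", 1L)[1]
  if (fmt != 1L)
    vd_stop(sprintf("'%s': unsupported TIFF sample format %d (need unsigned)",
                    path, fmt), "visdemand_format_error")
  offsets <- get_tag("strip_offsets")
  counts <- get_tag("strip_bytes")
  if (is.null(offsets))
    vd_stop(sprintf("'%s': TIFF lacks strip offsets", path),
            "visdemand_format_error")
  if (is.null(counts))
    counts <- rep(w * h * spp * (bits %/% 8L) %/% length(offsets),
                  length(offsets))
  data <- raw(0)
  for (k in seq_along(offsets)) {
    if (offsets[k] + counts[k] > length(bytes))
      vd_stop(sprintf("'%s': truncated TIFF (strip %d out of range)", path, k),
              "visdemand_io_error")
    data <- c(data, bytes[(offsets[k] + 1L):(offsets[k] + counts[k])])
  }
  need <- as.numeric(w) * h * spp * (bits %/% 8L)
  if (length(data) < need)
    vd_stop(sprintf("'%s': truncated TIFF image data", path),
            "visdemand_io_error")
  vals <- if (bits == 8L) {
    as.integer(data[seq_len(need)])
  } else {
    readBin(data, "integer", n = need %/% 2L, size = 2, signed = FALSE,
            endian = endian)
  }
  # TIFF is row-major, interleaved by sample.
  px <- array(0L, dim = c(h, w, spp))
  for (s in seq_len(spp))
    px[, , s] <- matrix(vals[seq(s, length(vals), by = spp)],
                        nrow = h, ncol = w, byrow = TRUE)
  list(pixels = px, bit_depth = bits)
}

write_tiff_gray16 <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  h <- nrow(pixels); w <- ncol(pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  data_off <- 8L
  data_len <- w * h * 2L
  ifd_off <- data_off + data_len
  writeBin(charToRaw("II"), con); w16(42L); w32(ifd_off)
  # samples row-major; writeBin of values > 32767 needs the two's-complement
  # trick since R lacks unsigned types
  vals <- as.integer(t(pixels))
  vals[vals > 32767L] <- vals[vals > 32767L] - 65536L
  writeBin(vals, con, size = 2, endian = "little")
  entry <- function(tag, typ, cnt, val) {
    w16(tag); w16(typ); w32(cnt); w32(val)
    if (typ == 3L && cnt == 1L) {
      # SHORT values are left-justified in the 4-byte slot: rewind and fix
      seek(con, seek(con) - 4L); w16(val); w16(0L)
    }
  }
  tags <- list(
    c(256L, 3L, 1L, w), c(257L, 3L, 1L, h), c(258L, 3L, 1L, 16L),
    c(259L, 3L, 1L, 1L), c(262L, 3L, 1L, 1L), c(273L, 4L, 1L, data_off),
    c(277L, 3L, 1L, 1L), c(278L, 3L, 1L, h), c(279L, 4L, 1L, data_len),
    c(284L, 3L, 1L, 1L)
  )
  w16(length(tags))
  for (tg in tags) entry(tg[1], tg[2], tg[3], tg[4])
  w32(0L)  # no next IFD
  invisible(path)
}
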