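# Minimal PNG writer used only to build test fixtures at run time, so the
# package's PNG reader is exercised against files produced by independent
# code. Emits valid non-interlaced PNGs (correct CRC-32 and zlib stream;
# verified against external decoders during development).

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) == 1L)
        bitwXor(-306674912L, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
    tab[n + 1L] <- c
  }
  tab
})

crc32_bytes <- function(bytes) {
  c <- -1L
  for (x in as.integer(bytes))
    c <- bitwXor(crc32_table[bitwAnd(bitwXor(c, x), 255L) + 1L],
                 bitwShiftR(c, 8L))
  bitwXor(c, -1L)
}

u32_be <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_be(length(data)), body, u32_be(crc32_bytes(body)))
}

# pixels: H x W matrix (gray) or H x W x 3 array (RGB); values on the scale
# of bit_depth. filter_type: PNG per-row filter to apply (0, 1, 2 or 4),
# letting tests exercise the unfiltering paths.
write_test_png <- function(pixels, path, bit_depth = 8L, filter_type = 0L) {
  if (is.matrix(pixels)) {
    spp <- 1L; color_type <- 0L
    h <- nrow(pixels); w <- ncol(pixels)
    sample_rows <- lapply(seq_len(h), function(i) as.integer(pixels[i, ]))
  } else {
    spp <- 3L; color_type <- 2L
    h <- dim(pixels)[1]; w <- dim(pixels)[2]
    sample_rows <- lapply(seq_len(h), function(i)
      as.integer(t(matrix(pixels[i, , ], w, 3))))
  }
  to_bytes <- function(v) {
    if (bit_depth == 8L) as.raw(v)
    else as.raw(as.vector(rbind(v %/% 256L, v %% 256L)))  # big-endian
  }
  bpp <- spp * (bit_depth %/% 8L)
  raw_rows <- lapply(sample_rows, to_bytes)
  filt <- function(cur, prev) {
    ci <- as.integer(cur); pi_ <- as.integer(prev)
    left <- c(rep(0L, bpp), head(ci, -bpp))
    upleft <- c(rep(0L, bpp), head(pi_, -bpp))
    switch(as.character(filter_type),
      "0" = cur,
      "1" = as.raw((ci - left) %% 256L),
      "2" = as.raw((ci - pi_) %% 256L),
      "4" = {
        p <- left + pi_ - upleft
        pa <- abs(p - left); pb <- abs(p - pi_); pc <- abs(p - upleft)
        pred <- ifelse(pa <= pb & pa <= pc, left, ifelse(pb <= pc, pi_, upleft))
        as.raw((ci - pred) %% 256L)
      })
  }
  scan <- raw(0)
  prev <- as.raw(rep(0L, w * bpp))
  for (i in seq_len(h)) {
    scan <- c(scan, as.raw(filter_type), filt(raw_rows[[i]], prev))
    prev <- raw_rows[[i]]
  }
  idat <- memCompress(scan, type = "gzip")  # yields a zlib stream
  ihdr <- c(u32_be(w), u32_be(h), as.raw(c(bit_depth, color_type, 0, 0, 0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}
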