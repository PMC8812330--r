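# Hand-written minimal multi-page grayscale TIFF with resolution tags
# (tiff::writeTIFF cannot emit XResolution, so calibration-metadata tests
# build their fixture byte by byte: little-endian, uncompressed, one
# strip per page).
write_tiff_with_resolution <- function(path, planes, xres, yres = xres,
                                       res_unit = 1L) {
  # res_unit: 1 = none (ImageJ px/um convention), 2 = inch, 3 = cm
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)
  n_pages <- length(planes)
  # layout: header (8) | per page: pixel data, rationals (16), IFD
  offset <- 8L
  meta <- list()
  for (p in seq_len(n_pages)) {
    h <- nrow(planes[[p]]); w <- ncol(planes[[p]])
    data_off <- offset
    rat_off <- data_off + w * h
    ifd_off <- rat_off + 16L
    meta[[p]] <- list(h = h, w = w, data_off = data_off, rat_off = rat_off,
                      ifd_off = ifd_off)
    offset <- ifd_off + 2L + 12L * 12L + 4L
  }
  w4(meta[[1]]$ifd_off)
  rational <- function(x) {
    den <- 10000L
    c(as.integer(round(x * den)), den)
  }
  for (p in seq_len(n_pages)) {
    m <- meta[[p]]
    writeBin(as.raw(as.integer(t(planes[[p]]))), con)   # row-major strip
    w4(rational(xres)); w4(rational(yres))
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count); w4(value)
    }
    w2(12L)                                   # 12 IFD entries
    entry(256L, 3L, 1L, m$w)                  # ImageWidth
    entry(257L, 3L, 1L, m$h)                  # ImageLength
    entry(258L, 3L, 1L, 8L)                   # BitsPerSample
    entry(259L, 3L, 1L, 1L)                   # Compression: none
    entry(262L, 3L, 1L, 1L)                   # Photometric: BlackIsZero
    entry(273L, 4L, 1L, m$data_off)           # StripOffsets
    entry(277L, 3L, 1L, 1L)                   # SamplesPerPixel
    entry(278L, 3L, 1L, m$h)                  # RowsPerStrip
    entry(279L, 4L, 1L, m$w * m$h)            # StripByteCounts
    entry(282L, 5L, 1L, m$rat_off)            # XResolution
    entry(283L, 5L, 1L, m$rat_off + 8L)       # YResolution
    entry(296L, 3L, 1L, res_unit)             # ResolutionUnit
    w4(if (p < n_pages) meta[[p + 1]]$ifd_off else 0L)
  }
  invisible(path)
}
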