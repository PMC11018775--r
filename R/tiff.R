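# Minimal baseline TIFF support: uncompressed, little-endian, single-sample
# 32-bit IEEE float, one strip per page. This covers exactly the dialect this
# package writes (no pre-installed R TIFF reader exists in the target
# environment); arbitrary third-party TIFFs are out of scope.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_bytes = 279L, sample_format = 339L)

# planes: list of numeric (Y, X) matrices, all the same size.
write_tiff_float <- function(planes, path) {
  stopifnot(length(planes) >= 1, all(vapply(planes, is.matrix, TRUE)))
  h <- nrow(planes[[1]]); w <- ncol(planes[[1]])
  if (!all(vapply(planes, function(p) nrow(p) == h && ncol(p) == w, TRUE)))
    stop("all planes must share one size")
  n <- length(planes)
  ifd_size <- 2L + 9L * 12L + 4L
  data_size <- as.integer(w * h * 4L)
  ifd_off <- 8L + (seq_len(n) - 1L) * (ifd_size + data_size)
  data_off <- ifd_off + ifd_size
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  wr2(42L); wr4(8L)
  entry <- function(tag, type, value) { # type 3 = SHORT, 4 = LONG
    wr2(tag); wr2(type); wr4(1L)
    if (type == 3L) { wr2(value); wr2(0L) } else wr4(value)
  }
  for (i in seq_len(n)) {
    wr2(9L)
    entry(TIFF_TAGS[["width"]], 4L, w)
    entry(TIFF_TAGS[["length"]], 4L, h)
    entry(TIFF_TAGS[["bits"]], 3L, 32L)
    entry(TIFF_TAGS[["compression"]], 3L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L)
    entry(TIFF_TAGS[["strip_offsets"]], 4L, data_off[i])
    entry(TIFF_TAGS[["rows_per_strip"]], 4L, h)
    entry(TIFF_TAGS[["strip_bytes"]], 4L, data_size)
    entry(TIFF_TAGS[["sample_format"]], 3L, 3L)
    wr4(if (i < n) ifd_off[i + 1L] else 0L)
    # row-major pixel data
    writeBin(as.numeric(t(planes[[i]])), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_tiff_float <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop("not a little-endian TIFF")
  ifd <- u32(4)
  planes <- list()
  while (ifd != 0) {
    ntag <- u16(ifd)
    tags <- list()
    for (k in seq_len(ntag)) {
      e <- ifd + 2 + (k - 1) * 12
      tag <- u16(e); type <- u16(e + 2)
      val <- if (type == 3L) u16(e + 8) else u32(e + 8)
      tags[[as.character(tag)]] <- val
    }
    gt <- function(id) tags[[as.character(TIFF_TAGS[[id]])]]
    if ((gt("compression") %||% 1L) != 1L) stop("compressed TIFF not supported")
    if ((gt("bits") %||% 0L) != 32L || (gt("sample_format") %||% 0L) != 3L)
      stop("only 32-bit float samples supported")
    w <- gt("width"); h <- gt("length"); off <- gt("strip_offsets")
    v <- readBin(raw[(off + 1):(off + w * h * 4)], "numeric", n = w * h,
                 size = 4, endian = "little")
    planes[[length(planes) + 1L]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    ifd <- u32(ifd + 2 + ntag * 12)
  }
  planes
}
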