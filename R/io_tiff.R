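# Minimal baseline TIFF I/O for grayscale image stacks.
#
# Scope: little-endian, uncompressed, single sample per pixel, one strip per
# page; 8- or 16-bit unsigned integer or 32-bit IEEE float. This covers the
# multi-page stacks the simulator writes and anything a microscope exports as
# plain uncompressed TIFF. Tiled, compressed, RGB or big-endian files are
# rejected with a clear error rather than mis-read.

TIFF_TAGS <- c(
  ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
  Compression = 259L, Photometric = 262L, StripOffsets = 273L,
  SamplesPerPixel = 277L, RowsPerStrip = 278L, StripByteCounts = 279L,
  SampleFormat = 339L
)

#' Write a grayscale image stack as a multi-page TIFF
#'
#' Pages are written uncompressed, little-endian, one strip per page.
#'
#' @param x a numeric matrix (single page) or 3-D array with dimensions
#'   `c(rows, cols, pages)`.
#' @param path output file path.
#' @param bits `16` (unsigned integer, values clamped to `[0, 65535]` and
#'   rounded), `8`, or `32` for IEEE single-precision float.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, bits = 16L) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (!bits %in% c(8L, 16L, 32L)) stop("bits must be 8, 16 or 32", call. = FALSE)
  ny <- dim(x)[1]; nx <- dim(x)[2]; np <- dim(x)[3]
  bytes_px <- bits %/% 8L
  fmt <- if (bits == 32L) 3L else 1L  # 3 = IEEE float, 1 = unsigned int

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  first_ifd <- 8L + nx * ny * np * bytes_px
  writeBin(first_ifd, con, size = 4, endian = "little")

  for (p in seq_len(np)) {
    page <- t(x[, , p])          # TIFF stores row-major (rows of the image)
    v <- as.vector(page)         # after t(): row-major order of original
    if (bits == 32L) {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      v <- pmax(0, pmin(round(v), 2^bits - 1))
      writeBin(as.integer(v), con, size = bytes_px, endian = "little")
    }
  }

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  page_bytes <- nx * ny * bytes_px
  ifd_size <- 2L + 10L * 12L + 4L
  for (p in seq_len(np)) {
    writeBin(10L, con, size = 2, endian = "little")
    entry(256, 4, 1, nx)
    entry(257, 4, 1, ny)
    entry(258, 3, 1, bits)
    entry(259, 3, 1, 1)        # no compression
    entry(262, 3, 1, 1)        # BlackIsZero
    entry(273, 4, 1, 8L + (p - 1L) * page_bytes)
    entry(277, 3, 1, 1)
    entry(278, 4, 1, ny)
    entry(279, 4, 1, page_bytes)
    entry(339, 3, 1, fmt)
    next_ifd <- if (p < np) first_ifd + p * ifd_size else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF
#'
#' Supports the uncompressed little-endian grayscale subset written by
#' [write_tiff()] (and equivalent exports from other software).
#'
#' @param path TIFF file path.
#' @return a 3-D numeric array `c(rows, cols, pages)`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  u16 <- function(off) as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2L) != 42L)
    stop("not a little-endian TIFF", call. = FALSE)

  pages <- list()
  ifd <- u32(4L)
  while (ifd != 0) {
    n_entries <- u16(ifd)
    tags <- list()
    for (e in seq_len(n_entries)) {
      off <- ifd + 2L + (e - 1L) * 12L
      tag <- u16(off); type <- u16(off + 2L); count <- u32(off + 4L)
      val <- if (type == 3L && count == 1L) u16(off + 8L) else u32(off + 8L)
      # multi-valued offsets (strips) resolved below if needed
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        val = val, off = off + 8L)
    }
    gv <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      t$val
    }
    if (gv(259, 1) != 1) stop("compressed TIFF not supported", call. = FALSE)
    if (gv(277, 1) != 1) stop("multi-sample TIFF not supported", call. = FALSE)
    nx <- gv(256); ny <- gv(257); bits <- gv(258, 8)
    fmt <- gv(339, 1)
    st <- tags[["273"]]; sc <- tags[["279"]]
    read_vals <- function(t) {
      if (t$count == 1L) return(t$val)
      base <- t$val
      sz <- if (t$type == 3L) 2L else 4L
      vapply(seq_len(t$count), function(i) {
        o <- base + (i - 1L) * sz
        if (sz == 2L) u16(o) else u32(o)
      }, numeric(1))
    }
    offsets <- read_vals(st)
    counts <- read_vals(sc)
    nbytes <- sum(counts)
    buf <- raw(nbytes)
    pos <- 1L
    for (i in seq_along(offsets)) {
      buf[pos:(pos + counts[i] - 1L)] <- raw[(offsets[i] + 1L):(offsets[i] + counts[i])]
      pos <- pos + counts[i]
    }
    v <- if (fmt == 3L && bits == 32L) {
      readBin(buf, "numeric", n = nx * ny, size = 4, endian = "little")
    } else if (bits == 16L) {
      readBin(buf, "integer", n = nx * ny, size = 2, signed = FALSE,
              endian = "little")
    } else if (bits == 8L) {
      as.integer(buf[seq_len(nx * ny)])
    } else stop("unsupported bit depth: ", bits, call. = FALSE)
    pages[[length(pages) + 1L]] <- t(matrix(v, nrow = nx, ncol = ny))
    ifd <- u32(ifd + 2L + n_entries * 12L)
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  out <- array(0, dim = c(ny, nx, length(pages)))
  for (p in seq_along(pages)) out[, , p] <- pages[[p]]
  out
}
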