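## Minimal baseline TIFF I/O (uncompressed, little-endian, grayscale).
##
## The toolchain this package runs under has no TIFF library, so atlas mask
## stacks and rendered section images are written/read with a small built-in
## codec. Scope is deliberately narrow: single-sample-per-pixel images,
## uint8/uint16/float32, one strip per page, no compression. This is enough
## for every file the package itself produces and keeps outputs byte-stable.

.tiff_types <- list(
  uint8   = list(bits = 8L,  fmt = 1L, size = 1L),
  uint16  = list(bits = 16L, fmt = 1L, size = 2L),
  float32 = list(bits = 32L, fmt = 3L, size = 4L)
)

#' Write a multi-page grayscale TIFF
#'
#' @param pages a matrix or list of equally sized numeric matrices
#'   (rows = image rows).
#' @param path output file path.
#' @param type pixel type: "uint8", "uint16" or "float32". Integer types are
#'   rounded and clamped to the representable range.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, type = c("uint16", "uint8", "float32")) {
  type <- match.arg(type)
  if (is.matrix(pages)) pages <- list(pages)
  if (!length(pages)) stopf("no pages to write")
  tp <- .tiff_types[[type]]
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  for (pg in pages)
    if (nrow(pg) != h || ncol(pg) != w) stopf("all pages must share dimensions")

  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")

  ## header
  writeBin(charToRaw("II"), con)
  w2(42L); w4(8L)                       # magic, offset of first IFD

  n <- length(pages)
  bytes_per_page <- h * w * tp$size
  ifd_size <- 2L + 10L * 12L + 4L       # 10 tags
  ## layout: header(8) | IFD1 data1 | IFD2 data2 | ...
  ifd_off <- 8L
  for (i in seq_len(n)) {
    data_off <- ifd_off + ifd_size
    next_ifd <- if (i < n) data_off + bytes_per_page else 0L
    entry <- function(tag, typ, count, value) { w2(tag); w2(typ); w4(count); w4(value) }
    ## SHORT values sit in the low bytes of the 4-byte field (little-endian)
    w2(10L)
    entry(256L, 4L, 1L, w)              # ImageWidth
    entry(257L, 4L, 1L, h)              # ImageLength
    entry(258L, 3L, 1L, tp$bits)        # BitsPerSample
    entry(259L, 3L, 1L, 1L)             # Compression: none
    entry(262L, 3L, 1L, 1L)             # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)       # StripOffsets
    entry(277L, 3L, 1L, 1L)             # SamplesPerPixel
    entry(278L, 4L, 1L, h)              # RowsPerStrip
    entry(279L, 4L, 1L, bytes_per_page) # StripByteCounts
    entry(339L, 3L, 1L, tp$fmt)         # SampleFormat
    w4(next_ifd)

    v <- as.vector(t(pages[[i]]))       # row-major
    if (type == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      maxv <- 2^tp$bits - 1
      v <- pmin(pmax(round(v), 0), maxv)
      if (type == "uint16") {
        ## writeBin has no unsigned 16-bit: fold into signed range
        vi <- as.integer(ifelse(v > 32767, v - 65536, v))
        writeBin(vi, con, size = 2, endian = "little")
      } else {
        writeBin(as.raw(v), con)
      }
    }
    ifd_off <- data_off + bytes_per_page
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_tiff()]
#'
#' Supports uncompressed little-endian grayscale pages (any strip layout).
#'
#' @param path file path.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stopf("not a TIFF file: %s", path)
  if (rawToChar(raw[1:2]) != "II") stopf("only little-endian TIFF supported")
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (u16(2) != 42L) stopf("bad TIFF magic in %s", path)

  pages <- list()
  ifd <- u32(4)
  while (ifd != 0) {
    nent <- u16(ifd)
    tags <- list()
    for (e in seq_len(nent)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u16(off); typ <- u16(off + 2); cnt <- u32(off + 4)
      val <- if (typ == 3 && cnt == 1) u16(off + 8) else u32(off + 8)
      ## multi-valued entries store an offset; resolve LONG/SHORT arrays
      if (cnt > 1) {
        ptr <- u32(off + 8)
        val <- if (typ == 3) vapply(seq_len(cnt), function(k) u16(ptr + 2 * (k - 1)), 1L)
               else vapply(seq_len(cnt), function(k) u32(ptr + 4 * (k - 1)), 1)
      }
      tags[[as.character(tag)]] <- val
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    bits <- tags[["258"]] %||% 8L
    if ((tags[["259"]] %||% 1L) != 1L) stopf("compressed TIFF not supported")
    fmt <- tags[["339"]] %||% 1L
    offs <- tags[["273"]]; counts <- tags[["279"]]
    buf <- raw[unlist(mapply(function(o, n) o + seq_len(n), offs, counts,
                             SIMPLIFY = FALSE))]
    npx <- h * w
    vals <- if (fmt == 3 && bits == 32) {
      readBin(buf, "double", npx, size = 4, endian = "little")
    } else if (bits == 16) {
      v <- readBin(buf, "integer", npx, size = 2, signed = FALSE, endian = "little")
      as.numeric(v)
    } else if (bits == 8) {
      as.numeric(as.integer(buf[seq_len(npx)]))
    } else stopf("unsupported bit depth %d", bits)
    pages[[length(pages) + 1]] <- matrix(vals, nrow = h, byrow = TRUE)
    ifd <- u32(ifd + 2 + nent * 12)
  }
  pages
}
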