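## Minimal TIFF codec: uncompressed, strip-based, grayscale, 8- or 16-bit,
## single or multi-page (IFD chain).  Deliberately small: microscopy export
## in this package always goes through write_tiff(), and read_tiff() accepts
## the common uncompressed grayscale layout produced by Fiji/"save as raw
## TIFF" style exporters.  Anything fancier (LZW, tiles, RGB TIFF) errors
## out loudly rather than guessing.

TIFF_TAGS <- c(
  ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
  Compression = 259L, Photometric = 262L, StripOffsets = 273L,
  SamplesPerPixel = 277L, RowsPerStrip = 278L, StripByteCounts = 279L
)

read_uint <- function(raw, endian) {
  sum(as.integer(raw) * 256^(if (endian == "little") seq_along(raw) - 1
                             else rev(seq_along(raw)) - 1))
}

#' Read a grayscale TIFF image or stack
#'
#' Supports uncompressed, strip-based, single-sample (grayscale) TIFF with
#' 8 or 16 bits per sample, both byte orders, and multi-page stacks.
#'
#' @param path file path.
#' @param frame_index 1-based page to read, or `NULL` for all pages.
#' @return a numeric matrix (one page) or list of matrices (all pages).
#' @export
read_tiff <- function(path, frame_index = NULL) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  endian <- if (raw[1] == as.raw(0x49)) "little"
            else if (raw[1] == as.raw(0x4d)) "big"
            else stop("not a TIFF file: ", path)
  if (read_uint(raw[3:4], endian) != 42L) stop("not a TIFF file: ", path)
  u <- function(off, n) read_uint(raw[(off + 1):(off + n)], endian)
  pages <- list()
  ifd <- u(4L, 4L)
  while (ifd != 0L) {
    nent <- u(ifd, 2L)
    tags <- list()
    for (i in seq_len(nent)) {
      e <- ifd + 2L + (i - 1L) * 12L
      tag <- u(e, 2L); typ <- u(e + 2L, 2L); cnt <- u(e + 4L, 4L)
      size <- c(1L, 1L, 2L, 4L, 8L)[typ]
      if (is.na(size)) { next }
      if (size * cnt <= 4L) {
        vals <- vapply(seq_len(cnt), function(k) u(e + 8L + (k - 1L) * size, size), numeric(1))
      } else {
        off <- u(e + 8L, 4L)
        vals <- vapply(seq_len(cnt), function(k) u(off + (k - 1L) * size, size), numeric(1))
      }
      tags[[as.character(tag)]] <- vals
    }
    gt <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    w <- gt(TIFF_TAGS[["ImageWidth"]]); h <- gt(TIFF_TAGS[["ImageLength"]])
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions")
    bits <- gt(TIFF_TAGS[["BitsPerSample"]], 8L)[1]
    comp <- gt(TIFF_TAGS[["Compression"]], 1L)[1]
    spp <- gt(TIFF_TAGS[["SamplesPerPixel"]], 1L)[1]
    if (comp != 1L) stop("unsupported TIFF compression scheme: ", comp)
    if (spp != 1L) stop("only single-sample (grayscale) TIFF is supported")
    if (!bits %in% c(8L, 16L)) stop("unsupported bit depth: ", bits)
    offs <- gt(TIFF_TAGS[["StripOffsets"]])
    cnts <- gt(TIFF_TAGS[["StripByteCounts"]])
    bytes <- unlist(lapply(seq_along(offs), function(k)
      raw[(offs[k] + 1):(offs[k] + cnts[k])]))
    if (bits == 8L) {
      vals <- as.integer(bytes)
    } else {
      m <- matrix(as.integer(bytes), nrow = 2L)
      vals <- if (endian == "little") m[1, ] + 256L * m[2, ] else m[2, ] + 256L * m[1, ]
    }
    pages[[length(pages) + 1L]] <- matrix(vals[seq_len(w * h)], nrow = h,
                                          ncol = w, byrow = TRUE)
    ifd <- u(ifd + 2L + nent * 12L, 4L)
  }
  if (length(pages) == 0L) stop("TIFF file contains no pages: ", path)
  if (is.null(frame_index)) return(pages)
  if (frame_index < 1L || frame_index > length(pages))
    stop("frame_index ", frame_index, " out of range (stack has ",
         length(pages), " pages)")
  pages[[frame_index]]
}

uint_bytes <- function(x, n) as.raw(x %/% 256^(0:(n - 1)) %% 256)  # little-endian

#' Write a grayscale TIFF image or stack
#'
#' Writes uncompressed little-endian TIFF, 8-bit (values clamped to 0..255)
#' or 16-bit, one strip per page.
#'
#' @param img numeric matrix or list of matrices (pages of a stack).
#' @param path output path.
#' @param bits bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, bits = 8L) {
  pages <- if (is.list(img)) img else list(img)
  stopifnot(bits %in% c(8L, 16L))
  maxv <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  ## layout: header | page1 pixels | page1 IFD | page2 pixels | page2 IFD | ...
  pix <- lapply(pages, function(m) {
    v <- round(pmin(pmax(as.numeric(t(m)), 0), maxv))
    if (bits == 8L) as.raw(v) else {
      lo <- as.raw(v %% 256); hi <- as.raw(v %/% 256)
      as.vector(rbind(lo, hi))
    }
  })
  n_entries <- 9L
  ifd_len <- 2L + n_entries * 12L + 4L
  np <- length(pages)
  data_off <- integer(np); ifd_off <- integer(np)
  pos <- 8L
  for (p in seq_len(np)) {
    data_off[p] <- pos
    ifd_off[p] <- pos + length(pix[[p]])
    pos <- ifd_off[p] + ifd_len
  }
  entry <- function(tag, typ, cnt, val)
    c(uint_bytes(tag, 2L), uint_bytes(typ, 2L), uint_bytes(cnt, 4L),
      uint_bytes(val, 4L))
  blobs <- lapply(seq_len(np), function(p) {
    m <- pages[[p]]
    next_ifd <- if (p < np) ifd_off[p + 1L] else 0L
    ifd <- c(
      uint_bytes(n_entries, 2L),
      entry(256L, 3L, 1L, ncol(m)),            # ImageWidth
      entry(257L, 3L, 1L, nrow(m)),            # ImageLength
      entry(258L, 3L, 1L, bits),               # BitsPerSample
      entry(259L, 3L, 1L, 1L),                 # Compression = none
      entry(262L, 3L, 1L, 1L),                 # Photometric = BlackIsZero
      entry(273L, 4L, 1L, data_off[p]),        # StripOffsets
      entry(277L, 3L, 1L, 1L),                 # SamplesPerPixel
      entry(278L, 3L, 1L, nrow(m)),            # RowsPerStrip
      entry(279L, 4L, 1L, length(pix[[p]])),   # StripByteCounts
      uint_bytes(next_ifd, 4L)
    )
    c(pix[[p]], ifd)
  })
  header <- c(as.raw(c(0x49, 0x49, 0x2a, 0x00)), uint_bytes(ifd_off[1], 4L))
  writeBin(c(header, unlist(blobs)), con)
  invisible(path)
}

#' Number of pages in a TIFF stack
#' @param path file path.
#' @return integer page count.
#' @export
tiff_page_count <- function(path) length(read_tiff(path))
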