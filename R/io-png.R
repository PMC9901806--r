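## Minimal PNG codec built on base R's zlib bindings (memCompress emits
## RFC-1950 zlib streams, which is exactly what IDAT requires).  Supports
## 8-bit grayscale and RGB/RGBA, all five scanline filters on read, filter 0
## on write.  Used for fixture round-trips and detection overlay output.

## 32-bit XOR on unsigned values stored as doubles: R's bitwXor only takes
## signed ints, so operate on 16-bit halves.
xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

crc32_table <- local({
  tab <- numeric(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (c %% 2 == 1) xor32(3988292384, c %/% 2) else c %/% 2
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- 4294967295  # 0xFFFFFFFF
  for (v in as.integer(bytes)) {
    idx <- bitwXor(as.integer(crc %% 256), v)
    crc <- xor32(crc %/% 256, crc32_table[idx + 1L])
  }
  xor32(crc, 4294967295)
}

adler32 <- function(bytes) {
  a <- 1; b <- 0
  v <- as.integer(bytes)
  ## process in chunks so the running sums stay exact doubles
  n <- length(v)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + 4095L)
    seg <- v[i:j]
    a_new <- (a + cumsum(seg))
    b <- (b + sum(a_new)) %% 65521
    a <- a_new[length(a_new)] %% 65521
    i <- j + 1L
  }
  b * 65536 + a
}

u32be <- function(x) as.raw(c(x %/% 2^24, x %/% 2^16, x %/% 2^8, x) %% 256)

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

#' Write an 8-bit PNG image
#'
#' @param img numeric matrix (grayscale, values clamped to 0..255) or an
#'   array `h x w x 3` (RGB).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  if (is.matrix(img)) {
    h <- nrow(img); w <- ncol(img); ch <- 1L; ctype <- 0L
    px <- round(pmin(pmax(img, 0), 255))
    rows <- lapply(seq_len(h), function(y) as.raw(px[y, ]))
  } else if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L) {
    h <- dim(img)[1]; w <- dim(img)[2]; ch <- 3L; ctype <- 2L
    px <- round(pmin(pmax(img, 0), 255))
    rows <- lapply(seq_len(h), function(y) as.raw(as.vector(t(px[y, , ]))))
  } else stop("img must be a matrix or an h x w x 3 array")
  scan <- unlist(lapply(rows, function(r) c(as.raw(0L), r)))  # filter 0
  ihdr <- c(u32be(w), u32be(h), as.raw(c(8L, ctype, 0L, 0L, 0L)))
  idat <- memCompress(scan, type = "gzip")
  out <- c(
    as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", idat),
    png_chunk("IEND", raw(0))
  )
  writeBin(out, path)
  invisible(path)
}

paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

#' Read an 8-bit PNG image
#'
#' Handles grayscale, grayscale+alpha, RGB and RGBA at bit depth 8 (alpha is
#' dropped; RGB is returned as an array). All five PNG scanline filters are
#' unfiltered.
#'
#' @param path file path.
#' @return numeric matrix (grayscale) or `h x w x 3` array (RGB).
#' @export
read_png <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(raw) < 8L || !identical(raw[1:8], sig)) stop("not a PNG file: ", path)
  pos <- 8L
  idat <- raw(0)
  w <- h <- depth <- ctype <- NULL
  while (pos + 8L <= length(raw)) {
    len <- sum(as.integer(raw[(pos + 1):(pos + 4)]) * 256^(3:0))
    type <- rawToChar(raw[(pos + 5):(pos + 8)])
    data <- if (len > 0) raw[(pos + 9):(pos + 8 + len)] else raw(0)
    if (type == "IHDR") {
      w <- sum(as.integer(data[1:4]) * 256^(3:0))
      h <- sum(as.integer(data[5:8]) * 256^(3:0))
      depth <- as.integer(data[9]); ctype <- as.integer(data[10])
      if (depth != 8L) stop("only bit depth 8 PNG is supported")
      if (as.integer(data[13]) != 0L) stop("interlaced PNG is not supported")
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  ch <- switch(as.character(ctype), "0" = 1L, "2" = 3L, "4" = 2L, "6" = 4L,
               stop("unsupported PNG color type: ", ctype))
  scan <- as.integer(memDecompress(idat, type = "gzip"))
  stride <- w * ch
  prev <- integer(stride)
  out <- matrix(0L, h, stride)
  for (y in seq_len(h)) {
    off <- (y - 1L) * (stride + 1L)
    f <- scan[off + 1L]
    cur <- scan[(off + 2L):(off + 1L + stride)]
    left <- function(v) c(integer(ch), v[seq_len(stride - ch)])
    cur <- switch(as.character(f),
      "0" = cur,
      "1" = { r <- cur; for (i in (ch + 1):stride) r[i] <- (r[i] + r[i - ch]) %% 256L; r },
      "2" = (cur + prev) %% 256L,
      "3" = { r <- cur
              for (i in seq_len(stride)) {
                a <- if (i > ch) r[i - ch] else 0L
                r[i] <- (r[i] + (a + prev[i]) %/% 2L) %% 256L
              }; r },
      "4" = { r <- cur
              for (i in seq_len(stride)) {
                a <- if (i > ch) r[i - ch] else 0L
                cc <- if (i > ch) prev[i - ch] else 0L
                r[i] <- (r[i] + paeth(a, prev[i], cc)) %% 256L
              }; r },
      stop("bad PNG filter byte: ", f))
    out[y, ] <- cur
    prev <- cur
  }
  if (ch == 1L) return(out)
  if (ch == 2L) return(out[, seq(1L, stride, by = 2L), drop = FALSE])
  arr <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) arr[, , k] <- out[, seq(k, stride, by = ch), drop = FALSE]
  arr
}
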