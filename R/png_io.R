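# Minimal PNG codec for thickness images: 8-bit RGB, no interlace,
# filter 0, and a zlib stream made of *stored* (uncompressed) deflate
# blocks.  Hand-rolled because no PNG-capable R package is available in
# the target environment; files are bit-exact reproducible and readable
# by any standards-compliant viewer.

crc32_table <- local({
  poly <- -306674912L # 0xEDB88320 as signed 32-bit
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L))
           else bitwShiftR(c, 1L)
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L # 0xFFFFFFFF
  v <- as.integer(bytes)
  for (b in v) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(crc32_table[idx + 1], bitwShiftR(crc, 8L))
  }
  bitwXor(crc, -1L)
}

adler32 <- function(bytes) {
  d <- as.numeric(bytes)
  n <- length(d)
  a <- (1 + sum(d)) %% 65521
  b <- (n + sum((n - seq_len(n) + 1) * d)) %% 65521
  b * 65536 + a
}

uint_to_raw_be <- function(x, width = 4) {
  out <- raw(width)
  for (i in width:1) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_to_uint_be <- function(r) sum(as.numeric(r) * 256^((length(r) - 1):0))

# signed 32-bit int (as produced by crc32()) -> unsigned double
int_to_uint <- function(x) if (x < 0) x + 2^32 else as.numeric(x)

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- int_to_uint(crc32(body))
  c(uint_to_raw_be(length(data)), body, uint_to_raw_be(crc))
}

# zlib stream with stored deflate blocks (max 65535 bytes each)
zlib_stored <- function(data) {
  n <- length(data)
  starts <- seq(1, max(n, 1), by = 65535L)
  blocks <- lapply(seq_along(starts), function(i) {
    s <- starts[i]
    e <- min(s + 65534L, n)
    len <- e - s + 1L
    c(as.raw(if (i == length(starts)) 1L else 0L),      # BFINAL + BTYPE 00
      as.raw(c(len %% 256L, len %/% 256L)),             # LEN little-endian
      as.raw(c(255L - len %% 256L, 255L - len %/% 256L)), # NLEN = ~LEN
      data[s:e])
  })
  c(as.raw(c(0x78, 0x01)), do.call(c, blocks), uint_to_raw_be(adler32(data)))
}

#' Write a thickness image as an 8-bit RGB PNG
#'
#' The file is named `<patient_id>_thickness.png` when `path` is a
#' directory.  Round trips bit-exactly through [read_thickness_png()].
#'
#' @param image A [thickness_image()].
#' @param path Output file path, or an existing directory.
#' @return The file path, invisibly.
#' @export
write_thickness_png <- function(image, path) {
  stopifnot(inherits(image, "thickness_image"))
  if (dir.exists(path))
    path <- file.path(path, paste0(image$patient_id, "_thickness.png"))
  px <- image$pixels
  d <- dim(px)
  # scanlines: per row, filter byte 0 then RGB interleaved across columns
  inter <- as.vector(aperm(px, c(3, 2, 1))) # channel fastest, then col, row
  sl <- rbind(0L, matrix(as.integer(inter), nrow = 3 * d[2]))
  raw_data <- as.raw(as.vector(sl))
  ihdr <- c(uint_to_raw_be(d[2]), uint_to_raw_be(d[1]),
            as.raw(c(8L, 2L, 0L, 0L, 0L))) # depth 8, RGB, no interlace
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_stored(raw_data)),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a thickness-image PNG
#'
#' Supports the subset written by [write_thickness_png()] (8-bit RGB,
#' filter 0, stored deflate blocks) and verifies chunk CRCs.
#'
#' @param path PNG file path.
#' @param patient_id Patient id; by default parsed from the file name
#'   (`<patient_id>_thickness.png`).
#' @param condition Optional class label to attach.
#' @return A [thickness_image()].
#' @export
read_thickness_png <- function(path, patient_id = NULL,
                               condition = NA_character_) {
  bytes <- readBin(path, "raw", file.size(path))
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(bytes) < 8 || !identical(bytes[1:8], sig))
    stop("not a PNG file: ", path)
  pos <- 9
  width <- height <- NULL
  idat <- raw(0)
  while (pos + 7 <= length(bytes)) {
    len <- raw_to_uint_be(bytes[pos:(pos + 3)])
    type <- rawToChar(bytes[(pos + 4):(pos + 7)])
    data <- if (len > 0) bytes[(pos + 8):(pos + 7 + len)] else raw(0)
    stored_crc <- raw_to_uint_be(bytes[(pos + 8 + len):(pos + 11 + len)])
    if (stored_crc != int_to_uint(crc32(c(bytes[(pos + 4):(pos + 7)], data))))
      stop("PNG chunk CRC mismatch in ", type, " chunk of ", path)
    if (type == "IHDR") {
      width <- raw_to_uint_be(data[1:4])
      height <- raw_to_uint_be(data[5:8])
      if (as.integer(data[9]) != 8 || as.integer(data[10]) != 2)
        stop("unsupported PNG format (need 8-bit RGB): ", path)
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12 + len
  }
  # parse zlib stream of stored blocks
  if (length(idat) < 2) stop("PNG has no image data: ", path)
  p <- 3
  payload <- raw(0)
  repeat {
    hdr <- as.integer(idat[p])
    if (bitwAnd(bitwShiftR(hdr, 1L), 3L) != 0L)
      stop("unsupported deflate block type (only stored blocks readable)")
    len <- as.integer(idat[p + 1]) + 256L * as.integer(idat[p + 2])
    payload <- c(payload, if (len > 0) idat[(p + 5):(p + 4 + len)] else raw(0))
    p <- p + 5 + len
    if (bitwAnd(hdr, 1L) == 1L) break
  }
  stride <- 1 + 3 * width
  sl <- matrix(as.integer(payload), nrow = stride)
  if (any(sl[1, ] != 0L)) stop("unsupported PNG row filter (only 0 readable)")
  px <- aperm(array(sl[-1, ], c(3, width, height)), c(3, 2, 1))
  storage.mode(px) <- "integer"
  if (is.null(patient_id))
    patient_id <- sub("_thickness\\.png$", "", basename(path))
  thickness_image(patient_id, px, condition)
}
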