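# Minimal baseline TIFF I/O (uncompressed, little-endian, grayscale).
#
# The analysis pipeline exchanges images as plain grayscale TIFF: 16-bit
# unsigned for camera frames and label maps, 32-bit IEEE float for pH maps.
# Only the baseline feature set is implemented (single strip per page,
# no compression); this is sufficient for every file the package reads or
# writes and keeps the package free of binary dependencies.

TAG_WIDTH <- 256L
TAG_LENGTH <- 257L
TAG_BITS <- 258L
TAG_COMPRESSION <- 259L
TAG_PHOTOMETRIC <- 262L
TAG_DESCRIPTION <- 270L
TAG_STRIP_OFFSETS <- 273L
TAG_SAMPLES <- 277L
TAG_ROWS_PER_STRIP <- 278L
TAG_STRIP_BYTES <- 279L
TAG_SAMPLE_FORMAT <- 339L

#' Write matrices as a multi-page grayscale TIFF
#'
#' @param images a matrix or list of matrices (rows = y, columns = x).
#' @param path output file path.
#' @param bits 16 (unsigned integer, values clipped to 0..65535 and
#'   rounded) or 32 (IEEE single-precision float).
#' @param descriptions optional character vector of per-page descriptions
#'   (e.g. channel names), recycled to the number of pages.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(images, path, bits = 16L, descriptions = NULL) {
  if (is.matrix(images)) images <- list(images)
  if (!length(images) || !all(vapply(images, is.matrix, TRUE)))
    stopf("`images` must be a matrix or a non-empty list of matrices")
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 32L)) stopf("`bits` must be 16 or 32")
  if (!is.null(descriptions))
    descriptions <- rep_len(as.character(descriptions), length(images))
  # precompute the whole layout (header, then per page: pixel data,
  # description string, IFD) so every IFD can point at the next one
  n_pages <- length(images)
  desc_raws <- vector("list", n_pages)
  n_entries <- integer(n_pages)
  for (i in seq_len(n_pages)) {
    has_desc <- !is.null(descriptions)
    n_entries[[i]] <- 10L + has_desc
    if (has_desc) {
      dr <- c(charToRaw(descriptions[[i]]), as.raw(0L))
      if (length(dr) %% 2L == 1L) dr <- c(dr, as.raw(0L))
      desc_raws[[i]] <- dr
    }
  }
  data_off <- desc_off <- ifd_off <- numeric(n_pages)
  pos <- 8
  for (i in seq_len(n_pages)) {
    nbytes <- nrow(images[[i]]) * ncol(images[[i]]) * (bits / 8)
    data_off[[i]] <- pos
    pos <- pos + nbytes
    desc_off[[i]] <- pos
    pos <- pos + length(desc_raws[[i]])
    ifd_off[[i]] <- pos
    pos <- pos + 2 + 12 * n_entries[[i]] + 4
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con)
  wr2(42L)
  wr4(ifd_off[[1]])
  for (i in seq_len(n_pages)) {
    m <- images[[i]]
    h <- nrow(m)
    w <- ncol(m)
    v <- as.vector(t(m))  # row-major
    if (bits == 16L) {
      v <- pmin(pmax(round(v), 0), 65535)
      writeBin(as.integer(v), con, size = 2, endian = "little")
    } else {
      writeBin(as.double(v), con, size = 4, endian = "little")
    }
    if (!is.null(desc_raws[[i]])) writeBin(desc_raws[[i]], con)
    entries <- list(
      list(TAG_WIDTH, 3L, 1L, w),
      list(TAG_LENGTH, 3L, 1L, h),
      list(TAG_BITS, 3L, 1L, bits),
      list(TAG_COMPRESSION, 3L, 1L, 1L),
      list(TAG_PHOTOMETRIC, 3L, 1L, 1L)
    )
    if (!is.null(desc_raws[[i]]))
      entries <- c(entries, list(list(TAG_DESCRIPTION, 2L,
                                      length(desc_raws[[i]]),
                                      desc_off[[i]])))
    entries <- c(entries, list(
      list(TAG_STRIP_OFFSETS, 4L, 1L, data_off[[i]]),
      list(TAG_SAMPLES, 3L, 1L, 1L),
      list(TAG_ROWS_PER_STRIP, 3L, 1L, h),
      list(TAG_STRIP_BYTES, 4L, 1L, h * w * (bits / 8)),
      list(TAG_SAMPLE_FORMAT, 3L, 1L, if (bits == 32L) 3L else 1L)
    ))
    wr2(length(entries))
    for (e in entries) {
      wr2(e[[1]])
      wr2(e[[2]])
      wr4(e[[3]])
      if (e[[2]] == 3L) {
        wr2(e[[4]]); wr2(0L)
      } else {
        wr4(e[[4]])
      }
    }
    wr4(if (i == n_pages) 0L else ifd_off[[i + 1L]])
  }
  invisible(path)
}

#' Read a grayscale TIFF written by [write_tiff()]
#'
#' Supports uncompressed little-endian grayscale baseline TIFF with one
#' sample per pixel (16-bit unsigned or 32-bit float), one or more pages.
#'
#' @param path file path.
#' @return a list of matrices; each carries its page description (if any)
#'   as attribute `"description"`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II") stopf("only little-endian TIFF supported")
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.double(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (u16(2) != 42) stopf("not a TIFF file")
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd + 2 + 12 * (k - 1)
      tag <- u16(e)
      typ <- u16(e + 2)
      cnt <- u32(e + 4)
      val <- if (typ == 3 && cnt == 1) u16(e + 8) else u32(e + 8)
      tags[[as.character(tag)]] <- list(type = typ, count = cnt, value = val)
    }
    need <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) {
        if (is.null(default)) stopf("missing TIFF tag %d", tag)
        return(default)
      }
      t$value
    }
    w <- need(TAG_WIDTH)
    h <- need(TAG_LENGTH)
    bits <- need(TAG_BITS)
    if (need(TAG_COMPRESSION, 1) != 1) stopf("compressed TIFF not supported")
    fmt <- need(TAG_SAMPLE_FORMAT, 1)
    off <- need(TAG_STRIP_OFFSETS)
    npx <- w * h
    bytes <- raw[off + seq_len(npx * bits / 8)]
    v <- if (bits == 16) {
      readBin(bytes, "integer", n = npx, size = 2, signed = FALSE,
              endian = "little")
    } else if (bits == 32 && fmt == 3) {
      readBin(bytes, "numeric", n = npx, size = 4, endian = "little")
    } else stopf("unsupported TIFF sample layout (%d bits, format %d)",
                 bits, fmt)
    m <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    d <- tags[[as.character(TAG_DESCRIPTION)]]
    if (!is.null(d)) {
      s <- raw[d$value + seq_len(d$count)]
      s <- s[seq_len(max(which(s != 0), 0))]
      attr(m, "description") <- rawToChar(s)
    }
    pages <- c(pages, list(m))
    ifd <- u32(ifd + 2 + 12 * n)
  }
  pages
}
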