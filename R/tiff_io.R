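# Minimal multi-page TIFF codec for floating-point grayscale images.
#
# Mainstream R TIFF bindings store normalized integer samples, which cannot
# round-trip floating-point voxel intensities or surface positions exactly.
# This codec writes plain uncompressed little-endian TIFF with
# SampleFormat = IEEEFP at 32 or 64 bits per sample, one strip per page,
# and reads back exactly what it wrote. It is intentionally narrow: it is
# not a general TIFF reader.

.TIFF_TYPE_SHORT <- 3L
.TIFF_TYPE_LONG <- 4L

.tiff_entry <- function(tag, type, count, value) {
  val <- raw(4)
  if (type == .TIFF_TYPE_SHORT) {
    v <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
    val[seq_along(v)] <- v
  } else {
    val <- writeBin(as.integer(value), raw(), size = 4, endian = "little")
  }
  c(
    writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    val
  )
}

#' Write a list of numeric matrices as a float multi-page TIFF
#'
#' @param pages list of numeric matrices, all with identical dimensions.
#'   Rows map to TIFF image length and columns to image width.
#' @param path output file path.
#' @param bits bits per sample, 32 or 64. 64 preserves R doubles exactly.
#' @return `path`, invisibly.
#' @keywords internal
write_float_tiff <- function(pages, path, bits = 64L) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, bits %in% c(32L, 64L))
  dims <- dim(pages[[1L]])
  ok <- vapply(pages, function(p) is.matrix(p) && identical(dim(p), dims), logical(1))
  if (!all(ok)) stop("all TIFF pages must be matrices with identical dimensions")
  height <- dims[1L]
  width <- dims[2L]
  bytes_px <- bits %/% 8L
  strip_bytes <- height * width * bytes_px

  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  first_ifd <- 8L
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")

  offset <- first_ifd
  for (i in seq_along(pages)) {
    data_offset <- offset + ifd_size
    next_ifd <- if (i < length(pages)) data_offset + strip_bytes else 0L
    entries <- c(
      .tiff_entry(256L, .TIFF_TYPE_LONG, 1L, width),        # ImageWidth
      .tiff_entry(257L, .TIFF_TYPE_LONG, 1L, height),       # ImageLength
      .tiff_entry(258L, .TIFF_TYPE_SHORT, 1L, bits),        # BitsPerSample
      .tiff_entry(259L, .TIFF_TYPE_SHORT, 1L, 1L),          # Compression: none
      .tiff_entry(262L, .TIFF_TYPE_SHORT, 1L, 1L),          # Photometric: BlackIsZero
      .tiff_entry(273L, .TIFF_TYPE_LONG, 1L, data_offset),  # StripOffsets
      .tiff_entry(278L, .TIFF_TYPE_LONG, 1L, height),       # RowsPerStrip
      .tiff_entry(279L, .TIFF_TYPE_LONG, 1L, strip_bytes),  # StripByteCounts
      .tiff_entry(339L, .TIFF_TYPE_SHORT, 1L, 3L)           # SampleFormat: IEEEFP
    )
    writeBin(as.integer(n_entries), con, size = 2, endian = "little")
    writeBin(entries, con)
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    # row-major pixel data
    writeBin(as.vector(t(pages[[i]])), con, size = bytes_px, endian = "little")
    offset <- data_offset + strip_bytes
  }
  invisible(path)
}

.read_u16 <- function(raw, pos) {
  sum(as.integer(raw[pos + 0:1]) * c(1, 256))
}
.read_u32 <- function(raw, pos) {
  sum(as.numeric(raw[pos + 0:3]) * c(1, 256, 65536, 16777216))
}

#' Read a float multi-page TIFF written by [write_float_tiff()]
#'
#' @param path file path.
#' @return list of numeric matrices, one per page.
#' @keywords internal
read_float_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 8L || rawToChar(raw[1:2]) != "II" || .read_u16(raw, 3L) != 42)
    stop("not a little-endian TIFF file: ", path)
  ifd <- .read_u32(raw, 5L)
  pages <- list()
  while (ifd != 0) {
    n <- .read_u16(raw, ifd + 1L)
    tags <- list()
    for (k in seq_len(n)) {
      base <- ifd + 2L + (k - 1L) * 12L
      tag <- .read_u16(raw, base + 1L)
      type <- .read_u16(raw, base + 3L)
      value <- if (type == .TIFF_TYPE_SHORT) .read_u16(raw, base + 9L) else .read_u32(raw, base + 9L)
      tags[[as.character(tag)]] <- value
    }
    need <- c("256", "257", "258", "273", "279")
    if (!all(need %in% names(tags))) stop("TIFF page missing required tags")
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
      stop("only uncompressed TIFF is supported")
    if (is.null(tags[["339"]]) || tags[["339"]] != 3)
      stop("only IEEE floating-point sample format is supported")
    bits <- tags[["258"]]
    if (!bits %in% c(32, 64)) stop("unsupported bits per sample: ", bits)
    width <- tags[["256"]]; height <- tags[["257"]]
    off <- tags[["273"]]; nbytes <- tags[["279"]]
    bytes_px <- bits / 8
    if (nbytes != width * height * bytes_px) stop("inconsistent TIFF strip size")
    vals <- readBin(raw[(off + 1):(off + nbytes)], what = "double",
                    n = width * height, size = bytes_px, endian = "little")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
    ifd <- .read_u32(raw, ifd + 2L + n * 12L + 1L)
  }
  pages
}
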