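## Minimal baseline TIFF I/O for single-channel 16-bit grayscale images.
## Only what the assay needs: uncompressed, one sample per pixel, strip
## layout. Intensities are stored as unsigned 16-bit counts.

TAG <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
         photometric = 262L, strip_offsets = 273L, samples = 277L,
         rows_per_strip = 278L, strip_counts = 279L, sample_format = 339L)

#' Write a grayscale matrix as a 16-bit TIFF
#'
#' Writes an uncompressed, single-strip, little-endian baseline TIFF.
#' Values are rounded and clipped to the 0..65535 range; the arbitrary
#' intensity units of the synthetic generator map 1:1 onto counts.
#'
#' @param img numeric matrix (rows = image rows).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(img, path) {
  stopifnot(is.matrix(img))
  h <- nrow(img); w <- ncol(img)
  v <- as.integer(pmin(65535, pmax(0, round(t(img)))))  # row-major
  v[v > 32767L] <- v[v > 32767L] - 65536L               # two's complement
  data_offset <- 8L
  n_bytes <- 2L * h * w
  ifd_offset <- data_offset + n_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(v, con, size = 2, endian = "little")
  entries <- list(
    c(TAG[["width"]], 4L, 1L, w),
    c(TAG[["length"]], 4L, 1L, h),
    c(TAG[["bits"]], 3L, 1L, 16L),
    c(TAG[["compression"]], 3L, 1L, 1L),
    c(TAG[["photometric"]], 3L, 1L, 1L),
    c(TAG[["strip_offsets"]], 4L, 1L, data_offset),
    c(TAG[["samples"]], 3L, 1L, 1L),
    c(TAG[["rows_per_strip"]], 4L, 1L, h),
    c(TAG[["strip_counts"]], 4L, 1L, n_bytes),
    c(TAG[["sample_format"]], 3L, 1L, 1L))
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(as.integer(e[1]), con, size = 2, endian = "little")
    writeBin(as.integer(e[2]), con, size = 2, endian = "little")
    writeBin(as.integer(e[3]), con, size = 4, endian = "little")
    if (e[2] == 3L) { # SHORT values are left-justified in the 4-byte slot
      writeBin(as.integer(e[4]), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(e[4]), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little") # no further IFD
  invisible(path)
}

#' Read a grayscale TIFF written by [write_tiff16()]
#'
#' Supports uncompressed single-sample baseline TIFFs (8- or 16-bit, either
#' byte order, one or more strips), which covers files produced by this
#' package and by common microscope export dialects.
#'
#' @param path file path.
#' @return numeric matrix of intensities.
#' @export
read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               endian = endian)
  if (u16(2) != 42L) stop("not a baseline TIFF: ", path)
  ifd <- u32(4)
  n_entries <- u16(ifd)
  tags <- list()
  for (k in seq_len(n_entries)) {
    off <- ifd + 2 + (k - 1) * 12
    code <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
    val <- if (count == 1L) {
      if (type == 3L) u16(off + 8) else u32(off + 8)
    } else {
      ptr <- u32(off + 8)
      vapply(seq_len(count) - 1L, function(i) {
        if (type == 3L) u16(ptr + 2L * i) else u32(ptr + 4L * i)
      }, integer(1))
    }
    tags[[as.character(code)]] <- val
  }
  need <- function(code, default = NULL) {
    v <- tags[[as.character(code)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", code, " missing")
      default
    } else v
  }
  w <- need(TAG[["width"]]); h <- need(TAG[["length"]])
  bits <- need(TAG[["bits"]], 1L)
  if (need(TAG[["compression"]], 1L) != 1L)
    stop("compressed TIFF not supported")
  if (need(TAG[["samples"]], 1L) != 1L)
    stop("multi-sample TIFF not supported")
  if (!bits %in% c(8L, 16L)) stop("unsupported bit depth: ", bits)
  offs <- need(TAG[["strip_offsets"]])
  cnts <- need(TAG[["strip_counts"]])
  bytes <- unlist(lapply(seq_along(offs), function(i)
    raw[(offs[i] + 1):(offs[i] + cnts[i])]))
  px <- if (bits == 16L) {
    readBin(bytes, "integer", n = w * h, size = 2, signed = FALSE,
            endian = endian)
  } else {
    as.integer(bytes[seq_len(w * h)])
  }
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}
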