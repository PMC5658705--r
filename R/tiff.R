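# Minimal multi-page grayscale TIFF I/O (uncompressed, little-endian,
# 8- or 16-bit unsigned). No TIFF-capable R package is available in the
# runtime this package targets, so the baseline format is implemented
# directly; it covers exactly what microscope acquisition software emits
# for raw stacks and nothing more.

.tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L)

#' Write a multi-page grayscale TIFF
#'
#' Writes one page per frame as uncompressed little-endian unsigned
#' integers. Values are clamped to the representable range and rounded.
#'
#' @param x an [image_stack] or a list of numeric matrices.
#' @param path output file path.
#' @param bits bits per sample, 8 or 16 (default).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, bits = 16L) {
  frames <- if (inherits(x, "image_stack")) x$frames else x
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(bits %in% c(8L, 16L), length(frames) >= 1L)
  vmax <- 2^bits - 1
  bytes_per <- bits / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  w16(42L)
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  offset <- 8L
  # layout: [header][page1 data][page1 IFD][page2 data][page2 IFD]...
  w32(offset + prod(dim(frames[[1]])) * bytes_per)  # offset of first IFD
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    nr <- nrow(f); nc <- ncol(f)
    data_bytes <- nr * nc * bytes_per
    v <- as.integer(pmin(pmax(round(t(f)), 0), vmax))  # row-major
    if (bits == 16L) {
      # writeBin size-2 expects signed 16-bit values
      writeBin(ifelse(v > 32767L, v - 65536L, v), con, size = 2,
               endian = "little")
    } else {
      writeBin(as.raw(v), con)
    }
    ifd_offset <- offset + data_bytes
    next_offset <- if (i < length(frames))
      ifd_offset + ifd_size + prod(dim(frames[[i + 1]])) * bytes_per else 0L
    entry <- function(tag, type, count, value) {
      w16(tag); w16(type); w32(count)
      if (type == .tiff_types[["SHORT"]] && count == 1L) {
        w16(value); w16(0L)
      } else w32(value)
    }
    w16(n_entries)
    entry(256L, 4L, 1L, nc)            # ImageWidth
    entry(257L, 4L, 1L, nr)            # ImageLength
    entry(258L, 3L, 1L, bits)          # BitsPerSample
    entry(259L, 3L, 1L, 1L)            # Compression: none
    entry(262L, 3L, 1L, 1L)            # Photometric: BlackIsZero
    entry(273L, 4L, 1L, offset)        # StripOffsets
    entry(277L, 3L, 1L, 1L)           # SamplesPerPixel
    entry(278L, 4L, 1L, nr)            # RowsPerStrip
    entry(279L, 4L, 1L, data_bytes)    # StripByteCounts
    w32(next_offset)
    offset <- ifd_offset + ifd_size
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports the subset written by [write_tiff]: uncompressed little- or
#' big-endian grayscale pages at 8 or 16 bits per sample, possibly split
#' into multiple strips.
#'
#' @param path TIFF file path.
#' @return A list of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file")
  magic <- rawToChar(raw[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop("not a TIFF file")
  rd <- function(at, size, n = 1L)
    readBin(raw[(at + 1):(at + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size > 2L)  # offsets stay < 2^31
  if (rd(2, 2) != 42L) stop("bad TIFF magic number")
  ifd <- rd(4, 4)
  pages <- list()
  while (ifd != 0L) {
    n <- rd(ifd, 2)
    tags <- list()
    for (k in seq_len(n)) {
      at <- ifd + 2L + (k - 1L) * 12L
      tag <- rd(at, 2); type <- rd(at + 2, 2); count <- rd(at + 4, 4)
      esize <- c(1L, 1L, 2L, 4L, 8L)[type]
      vals <- if (esize * count <= 4L) {
        rd(at + 8, esize, count)
      } else {
        rd(rd(at + 8, 4), esize, count)
      }
      tags[[as.character(tag)]] <- vals
    }
    width <- tags[["256"]]; height <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]]
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
    if (comp != 1L) stop("only uncompressed TIFF is supported")
    if (!bits %in% c(8L, 16L)) stop("only 8/16-bit grayscale is supported")
    offs <- tags[["273"]]; counts <- tags[["279"]]
    px <- unlist(lapply(seq_along(offs), function(s) {
      nb <- counts[s]
      rd(offs[s], bits / 8L, nb / (bits / 8L))
    }))
    pages[[length(pages) + 1L]] <- matrix(as.numeric(px), nrow = height,
                                          ncol = width, byrow = TRUE)
    ifd <- rd(ifd + 2L + n * 12L, 4)
  }
  pages
}
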