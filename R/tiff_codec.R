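# Minimal baseline TIFF codec (uncompressed, strip-based, 8/16-bit,
# grayscale or interleaved RGB). No TIFF package ships with the target R
# environment, so the few tags the pipeline needs are read and written here
# directly; the codec is cross-validated against Python's tifffile in the
# test suite.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L,
               planar_config = 284L, sample_format = 339L)

# Read an 8/16-bit uncompressed TIFF. Returns a list(values = matrix or
# rows x cols x 3 array of raw counts, bits = 8 or 16).
read_tiff_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(as.integer(magic), c(0x49L, 0x49L))) "little"
            else if (identical(as.integer(magic), c(0x4DL, 0x4DL))) "big"
            else stop("format error: not a TIFF file: ", path, call. = FALSE)
  rd <- function(what, n, size, signed = TRUE) {
    if (size > 2L) signed <- TRUE  # readBin: unsigned only for sizes 1 and 2
    readBin(con, what, n = n, size = size, endian = endian, signed = signed)
  }
  if (rd("integer", 1, 2, signed = FALSE) != 42L) {
    stop("format error: bad TIFF magic in ", path, call. = FALSE)
  }
  ifd_offset <- rd("integer", 1, 4)
  seek(con, ifd_offset)
  n_entries <- rd("integer", 1, 2, signed = FALSE)
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- rd("integer", 1, 2, signed = FALSE)
    typ <- rd("integer", 1, 2, signed = FALSE)
    cnt <- rd("integer", 1, 4)
    val_bytes <- readBin(con, "raw", 4)
    size <- c(1L, 1L, 2L, 4L)[match(typ, c(1L, 2L, 3L, 4L))]
    if (is.na(size)) { tags[[as.character(tag)]] <- NULL; next }
    decode <- function(bytes, n) {
      readBin(bytes, "integer", n = n, size = size, endian = endian,
              signed = size > 2L)
    }
    total <- size * cnt
    vals <- if (total <= 4) {
      decode(val_bytes, cnt)
    } else {
      off <- readBin(val_bytes, "integer", 1, 4, endian = endian)
      here <- seek(con)
      seek(con, off)
      v <- rd("integer", cnt, size, signed = FALSE)
      seek(con, here)
      v
    }
    tags[[as.character(tag)]] <- vals
  }
  gt <- function(name, default = NULL) {
    v <- tags[[as.character(TIFF_TAGS[[name]])]]
    if (is.null(v)) default else v
  }
  if (!identical(gt("compression", 1L)[1], 1L)) {
    stop("format error: only uncompressed TIFF is supported", call. = FALSE)
  }
  spp <- gt("spp", 1L)[1]
  if (!spp %in% c(1L, 3L)) {
    stop("format error: SamplesPerPixel must be 1 or 3", call. = FALSE)
  }
  if (spp == 3L && !identical(gt("planar_config", 1L)[1], 1L)) {
    stop("format error: only interleaved RGB is supported", call. = FALSE)
  }
  bits <- unique(gt("bits", 8L))
  if (length(bits) != 1L || !bits %in% c(8L, 16L)) {
    stop("format error: only 8- or 16-bit samples are supported", call. = FALSE)
  }
  sf <- gt("sample_format", 1L)[1]
  if (!identical(sf, 1L)) {
    stop("format error: only unsigned integer samples are supported",
         call. = FALSE)
  }
  w <- gt("width"); h <- gt("length")
  if (is.null(w) || is.null(h)) stop("format error: missing dimensions",
                                     call. = FALSE)
  offsets <- gt("strip_offsets")
  counts <- gt("strip_bytes")
  if (is.null(offsets) || is.null(counts)) {
    stop("format error: missing strip layout", call. = FALSE)
  }
  sample_size <- bits / 8L
  n_samples <- as.numeric(w) * h * spp
  buf <- integer(0)
  for (s in seq_along(offsets)) {
    seek(con, offsets[s])
    n <- counts[s] / sample_size
    buf <- c(buf, rd("integer", n, sample_size, signed = FALSE))
  }
  if (length(buf) != n_samples) {
    stop("format error: truncated TIFF pixel data", call. = FALSE)
  }
  if (spp == 1L) {
    values <- matrix(buf, nrow = h, ncol = w, byrow = TRUE)
  } else {
    values <- array(0L, dim = c(h, w, 3L))
    for (ch in 1:3) {
      values[, , ch] <- matrix(buf[seq(ch, length(buf), by = 3L)],
                               nrow = h, ncol = w, byrow = TRUE)
    }
  }
  list(values = values, bits = as.integer(bits))
}

# Write an integer matrix as 8/16-bit uncompressed grayscale TIFF
# (little-endian, single strip).
write_tiff_gray <- function(values, path, bits) {
  stopifnot(bits %in% c(8L, 16L))
  h <- nrow(values); w <- ncol(values)
  smax <- 2^bits - 1
  v <- as.integer(round(values))
  if (any(v < 0 | v > smax)) {
    stop("pixel values out of range for ", bits, "-bit TIFF", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  sample_size <- bits %/% 8L
  data_offset <- 8L
  data_bytes <- h * w * sample_size
  ifd_offset <- data_offset + data_bytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  # pixel data, row-major
  row_major <- as.integer(t(values))
  if (bits == 16L) {
    writeBin(row_major, con, size = 2, endian = "little", useBytes = TRUE)
  } else {
    writeBin(as.raw(row_major), con)
  }
  entries <- list(
    c(256L, 3L, 1L, w),             # ImageWidth
    c(257L, 3L, 1L, h),             # ImageLength
    c(258L, 3L, 1L, bits),          # BitsPerSample
    c(259L, 3L, 1L, 1L),            # Compression: none
    c(262L, 3L, 1L, 1L),            # Photometric: BlackIsZero
    c(273L, 4L, 1L, data_offset),   # StripOffsets
    c(277L, 3L, 1L, 1L),            # SamplesPerPixel
    c(278L, 3L, 1L, h),             # RowsPerStrip
    c(279L, 4L, 1L, data_bytes),    # StripByteCounts
    c(339L, 3L, 1L, 1L)             # SampleFormat: unsigned int
  )
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(e[1], con, size = 2, endian = "little")
    writeBin(e[2], con, size = 2, endian = "little")
    writeBin(e[3], con, size = 4, endian = "little")
    if (e[2] == 3L) { # SHORT packed into 4-byte slot, left-justified
      writeBin(e[4], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(e[4], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little") # no next IFD
  invisible(path)
}
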