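#' Intensity image container
#'
#' A single-channel image on the raw count scale of the acquiring camera.
#' All sensitivity metrics are computed on raw counts, never on
#' display-normalized data: display normalization would corrupt the
#' scale-dependent SNR variants.
#'
#' @param values numeric matrix of nonnegative intensities in counts.
#' @param bit_depth 8 or 16.
#' @param source_id short identifier of the acquiring system or file.
#' @param dark_corrected logical, whether a dark frame was subtracted. Dark
#'   correction relaxes the upper bound check (values stay >= 0 only).
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(values, bit_depth, source_id = "",
                            dark_corrected = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!bit_depth %in% c(8L, 16L)) {
    stop("format error: bit_depth must be 8 or 16", call. = FALSE)
  }
  smax <- 2^bit_depth - 1
  if (any(values < 0)) stop("intensity values must be >= 0", call. = FALSE)
  if (!dark_corrected && any(values > smax)) {
    stop("intensity values exceed the saturation value ", smax, call. = FALSE)
  }
  structure(
    list(values = values, bit_depth = as.integer(bit_depth),
         saturation_value = smax, source_id = as.character(source_id),
         dark_corrected = isTRUE(dark_corrected)),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d, %d-bit%s, source '%s'\n",
              nrow(x$values), ncol(x$values), x$bit_depth,
              if (x$dark_corrected) ", dark-corrected" else "", x$source_id))
  invisible(x)
}

#' Read a phantom image
#'
#' Reads an 8- or 16-bit grayscale or RGB image from TIFF (uncompressed
#' baseline) or PNG, preserving integer counts without rescaling. RGB input
#' is reduced to one channel; the default rule keeps the red channel, where
#' near-infrared emission leaks predominantly on consumer sensors.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param bit_depth_hint optional override of the bit depth inferred from the
#'   file (useful for 8-bit data stored in 16-bit containers).
#' @param channel RGB reduction rule: `"red"` (default), `"green"`, `"blue"`,
#'   or `"luminance"` (Rec. 601 weights).
#' @return An [intensity_image()].
#' @export
read_image <- function(path, bit_depth_hint = NULL,
                       channel = c("red", "green", "blue", "luminance")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("I/O error: cannot read ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- read_tiff_raw(path)
    values <- raw$values
    bits <- raw$bits
  } else if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
    if (!bits %in% c(8L, 16L)) {
      stop("format error: unsupported PNG bit depth ", bits, call. = FALSE)
    }
    values <- round(arr * (2^bits - 1)) # readPNG rescales to [0, 1]
    if (length(dim(values)) == 3L && dim(values)[3] == 4L) {
      values <- values[, , 1:3, drop = FALSE] # drop alpha
    }
  } else {
    stop("format error: unsupported file type '", ext, "'", call. = FALSE)
  }
  if (length(dim(values)) == 3L) {
    values <- switch(channel,
      red = values[, , 1],
      green = values[, , 2],
      blue = values[, , 3],
      luminance = round(0.299 * values[, , 1] + 0.587 * values[, , 2] +
                        0.114 * values[, , 3])
    )
  }
  if (!is.null(bit_depth_hint)) bits <- as.integer(bit_depth_hint)
  intensity_image(values, bit_depth = bits, source_id = basename(path))
}

#' Write an intensity image
#'
#' Writes 8/16-bit grayscale TIFF (preferred) or 8-bit grayscale PNG.
#'
#' @param image an [intensity_image()].
#' @param path output path; format selected by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "intensity_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff_gray(image$values, path, image$bit_depth)
  } else if (ext == "png") {
    if (image$bit_depth != 8L) {
      stop("format error: PNG output is 8-bit only; use TIFF for 16-bit data",
           call. = FALSE)
    }
    png::writePNG(image$values / 255, path)
  } else {
    stop("format error: unsupported output type '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Subtract a dark frame
#'
#' Per-pixel `max(image - dark, 0)`: removes the camera offset and ambient
#' contribution measured with the excitation sources turned off. The result
#' is flagged as dark-corrected, which is recorded in every downstream
#' report.
#'
#' @param image,dark [intensity_image()]s of identical shape and bit depth.
#' @return A dark-corrected [intensity_image()].
#' @export
subtract_dark <- function(image, dark) {
  stopifnot(inherits(image, "intensity_image"),
            inherits(dark, "intensity_image"))
  if (!identical(dim(image$values), dim(dark$values))) {
    stop("geometry error: image and dark frame shapes differ", call. = FALSE)
  }
  if (image$bit_depth != dark$bit_depth) {
    stop("geometry error: image and dark frame bit depths differ",
         call. = FALSE)
  }
  intensity_image(pmax(image$values - dark$values, 0),
                  bit_depth = image$bit_depth,
                  source_id = image$source_id,
                  dark_corrected = TRUE)
}
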