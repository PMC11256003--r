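#' Build signal and background ROI masks
#'
#' Constructs, in pixel-index form, the three ROI families of the analysis:
#' per-well signal disks, per-well concentric background annuli with a 40%
#' larger outer radius ("b1"), and one well-sized disk in the distant
#' non-fluorescent region ("b2"). Pixel membership is by pixel-center
#' coordinates (0-based, inclusive boundary `|p - c| <= r`).
#'
#' Overlap policy: a b1 annulus pixel that falls inside any other well's
#' disk is removed; a pixel shared by two annuli is dropped from both. Well
#' disks take priority over annuli. This keeps every background pixel
#' exclusive, so a neighbor's fluorescence is never counted both as that
#' neighbor's signal and as this well's background.
#'
#' @param wells a `well_set` from [register_template()] / [segment_wells()].
#' @param image_shape integer (rows, cols).
#' @param b1_factor outer-radius factor of the b1 annulus (default 1.4).
#' @return An object of class `roi_mask_set`: `well_masks` and `b1_masks`
#'   (lists of 9 integer vectors of linear pixel indices), `b2_mask`,
#'   `image_shape`, `b1_factor`, `overlap_policy`.
#' @export
build_masks <- function(wells, image_shape, b1_factor = 1.4) {
  stopifnot(inherits(wells, "well_set"))
  image_shape <- as.integer(image_shape)
  r <- wells$radius
  router <- b1_factor * r
  # bounds check, 0-based pixel centers
  ctr <- rbind(wells$centers, matrix(wells$b2_center, 1, 2))
  rad <- c(rep(router, 9), wells$b2_radius)
  bad <- ctr[, 1] - rad < -0.5 | ctr[, 1] + rad > image_shape[2] - 0.5 |
         ctr[, 2] - rad < -0.5 | ctr[, 2] + rad > image_shape[1] - 0.5
  if (any(bad)) {
    stop("geometry error: ROI geometry extends outside the image",
         call. = FALSE)
  }
  well_masks <- lapply(seq_len(9), function(i)
    disk_indices(wells$centers[i, ], r, image_shape))
  outer_masks <- lapply(seq_len(9), function(i)
    disk_indices(wells$centers[i, ], router, image_shape))
  b1_masks <- lapply(seq_len(9), function(i)
    setdiff(outer_masks[[i]], well_masks[[i]]))
  all_wells <- unique(unlist(well_masks))
  # remove any well pixel from every annulus
  b1_masks <- lapply(b1_masks, function(m) setdiff(m, all_wells))
  # pixels shared by two annuli are dropped from both
  counts <- table(unlist(b1_masks))
  shared <- as.integer(names(counts)[counts > 1L])
  if (length(shared)) {
    b1_masks <- lapply(b1_masks, function(m) setdiff(m, shared))
  }
  b2_mask <- disk_indices(wells$b2_center, wells$b2_radius, image_shape)

  masks <- c(well_masks, b1_masks, list(b2_mask))
  if (any(vapply(masks, length, integer(1)) == 0L)) {
    stop("mask error: an ROI is empty after clipping", call. = FALSE)
  }
  structure(
    list(well_masks = well_masks, b1_masks = b1_masks, b2_mask = b2_mask,
         image_shape = image_shape, b1_factor = b1_factor,
         overlap_policy = "exclusive"),
    class = "roi_mask_set"
  )
}

#' @export
print.roi_mask_set <- function(x, ...) {
  cat(sprintf("<roi_mask_set> %d x %d: 9 wells (%s px), 9 b1 annuli, b2 (%d px)\n",
              x$image_shape[1], x$image_shape[2],
              paste(range(vapply(x$well_masks, length, integer(1))),
                    collapse = "-"),
              length(x$b2_mask)))
  invisible(x)
}

#' Intensity statistics under a mask
#'
#' @param image an [intensity_image()].
#' @param mask integer vector of linear pixel indices (column-major), e.g.
#'   one element of a [build_masks()] result.
#' @param std one of `"population"` (divisor n, the default) or `"sample"`
#'   (divisor n - 1).
#' @return An object of class `region_stats`: `mean`, `std`, `min`, `max`,
#'   `count`, `saturated_count`, `std_convention`.
#' @export
region_stats <- function(image, mask,
                         std = c("population", "sample")) {
  std <- match.arg(std)
  stopifnot(inherits(image, "intensity_image"))
  if (length(mask) == 0L) stop("mask error: empty mask", call. = FALSE)
  if (any(mask < 1L | mask > length(image$values))) {
    stop("mask error: mask indices outside the image", call. = FALSE)
  }
  v <- image$values[mask]
  n <- length(v)
  m <- mean(v)
  s2 <- sum((v - m)^2)
  sd_ <- if (std == "population") sqrt(s2 / n)
         else if (n > 1L) sqrt(s2 / (n - 1L)) else 0
  structure(
    list(mean = m, std = sd_, min = min(v), max = max(v), count = n,
         saturated_count = sum(v >= image$saturation_value),
         std_convention = std),
    class = "region_stats"
  )
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("<region_stats> mean %.4g, std %.4g (%s), range [%.4g, %.4g], n = %d (%d saturated)\n",
              x$mean, x$std, x$std_convention, x$min, x$max, x$count,
              x$saturated_count))
  invisible(x)
}

#' QC overlay of the ROI masks
#'
#' Writes an RGB PNG with the image in gray, well disks tinted green, b1
#' annuli yellow and the b2 disk blue.
#'
#' @param image an [intensity_image()].
#' @param masks a [build_masks()] result.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_qc_overlay <- function(image, masks, path) {
  v <- image$values
  g <- v / max(v, 1)
  rgb <- array(rep(g, 3), dim = c(dim(v), 3))
  tint <- function(idx, col, weight = 0.5) {
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[idx] <- (1 - weight) * plane[idx] + weight * col[ch]
      rgb[, , ch] <<- plane
    }
  }
  tint(unlist(masks$well_masks), c(0, 1, 0))
  tint(unlist(masks$b1_masks), c(1, 1, 0))
  tint(masks$b2_mask, c(0, 0.4, 1))
  png::writePNG(rgb, path)
  invisible(path)
}
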