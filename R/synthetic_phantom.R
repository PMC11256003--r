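#' Synthetic phantom rendering configuration
#'
#' Parameters of the synthetic sensitivity-versus-depth phantom image
#' generator. The generator emulates the statistical structure the analysis
#' assumes: each well is a disk whose amplitude decays exponentially with
#' depth (a single effective attenuation coefficient, not a full diffusion
#' model), blurred by a Gaussian whose width grows linearly with depth,
#' superimposed on a dim uniform background; per-pixel shot noise (Poisson)
#' and read noise (Gaussian) are applied, then the image is clipped and
#' quantized to the camera bit depth.
#'
#' Defaults describe a generic 16-bit camera: background 500 counts, surface
#' peak 20000 counts above background, effective attenuation 1 /mm (so the
#' deepest 3 mm well retains ~5% of the surface amplitude), blur growing from
#' 1 px at the surface by 1.5 px/mm, unit photon gain and 10 counts read
#' noise. See the package vignette for the reasoning behind these values.
#'
#' @param image_shape integer (rows, cols) of the rendered image.
#' @param bit_depth 8 or 16.
#' @param background_level uniform background in counts (>= 0).
#' @param peak_amplitude surface-well peak amplitude A0 above background, in
#'   counts (> 0).
#' @param attenuation_mu effective attenuation with depth, 1/mm (>= 0).
#' @param blur_sigma0 Gaussian blur sigma at zero depth, pixels.
#' @param blur_slope blur growth with depth, pixels/mm.
#' @param poisson_gain counts per photon for shot noise; 0 disables shot
#'   noise.
#' @param read_noise_sigma Gaussian read noise sigma in counts; 0 disables.
#' @param seed integer RNG seed; identical (config, template) pairs render
#'   bit-identical images.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(image_shape = c(300, 400),
                             bit_depth = 16,
                             background_level = 500,
                             peak_amplitude = 20000,
                             attenuation_mu = 1.0,
                             blur_sigma0 = 1.0,
                             blur_slope = 1.5,
                             poisson_gain = 1.0,
                             read_noise_sigma = 10,
                             seed = 1L) {
  if (!bit_depth %in% c(8L, 16L)) {
    stop("config error: bit_depth must be 8 or 16", call. = FALSE)
  }
  if (background_level < 0) stop("background_level must be >= 0", call. = FALSE)
  if (peak_amplitude <= 0) stop("peak_amplitude must be > 0", call. = FALSE)
  if (attenuation_mu < 0) stop("attenuation_mu must be >= 0", call. = FALSE)
  structure(
    list(image_shape = as.integer(image_shape),
         bit_depth = as.integer(bit_depth),
         background_level = background_level,
         peak_amplitude = peak_amplitude,
         attenuation_mu = attenuation_mu,
         blur_sigma0 = blur_sigma0,
         blur_slope = blur_slope,
         poisson_gain = poisson_gain,
         read_noise_sigma = read_noise_sigma,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Fit a template into an image frame
#'
#' Convenience constructor of the similarity transform that scales and
#' centers a design-unit template inside an image so that every well's b1
#' annulus (outer radius 1.4 r) and the b2 disk stay at least `margin` times
#' the transformed well radius away from the borders. Rotation is zero.
#'
#' @param template a [phantom_template()].
#' @param image_shape integer (rows, cols).
#' @param margin border clearance in units of the transformed well radius.
#' @return A [similarity_transform()]; x maps to column and y to row
#'   coordinates (0-based pixel centers).
#' @export
frame_transform <- function(template, image_shape, margin = 1) {
  pts <- rbind(template$well_centers, matrix(template$b2_center, 1, 2))
  lo <- apply(pts, 2, min) - 1.4 * template$well_radius
  hi <- apply(pts, 2, max) + 1.4 * template$well_radius
  span <- hi - lo                                # (x span, y span)
  avail <- c(image_shape[2], image_shape[1]) - 1 # (cols, rows) extent
  # leave `margin` well-radii of clearance on each side, in output pixels:
  # s * span + 2 * margin * s * r <= avail
  s <- min(avail / (span + 2 * margin * template$well_radius))
  if (s <= 0 || !is.finite(s)) {
    stop("geometry error: image too small for template", call. = FALSE)
  }
  mid_design <- (lo + hi) / 2
  mid_pixel <- avail / 2
  similarity_transform(s, 0, mid_pixel - s * mid_design)
}

#' Render a synthetic phantom image
#'
#' Renders the nine wells of a pixel-space template onto a background, then
#' applies the configured noise model and quantization. The noiseless signal
#' of well i is a disk of amplitude `A0 * exp(-attenuation_mu * depth_i)`
#' convolved with a Gaussian of sigma `blur_sigma0 + blur_slope * depth_i`,
#' added to `background_level`. Noise: Poisson on photon counts (if
#' `poisson_gain > 0`), then additive Gaussian read noise, then clipping to
#' `[0, 2^bit_depth - 1]` and rounding to integers.
#'
#' @param template a [phantom_template()] already in pixel space (e.g. via
#'   [apply_transform()] with a [frame_transform()]), fully inside the frame
#'   including the b1 annuli.
#' @param cfg a [synthetic_config()].
#' @return A list with elements `image` (an [intensity_image()]) and
#'   `ground_truth` (pixel-space template, per-well noiseless mean intensity
#'   under each well disk, the noiseless image matrix, and a config echo).
#' @export
render_phantom <- function(template, cfg) {
  stopifnot(inherits(template, "phantom_template"),
            inherits(cfg, "synthetic_config"))
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]
  check_template_in_frame(template, c(nr, nc))

  noiseless <- matrix(cfg$background_level, nr, nc)
  amps <- cfg$peak_amplitude * exp(-cfg$attenuation_mu * template$depths_mm)
  sigmas <- cfg$blur_sigma0 + cfg$blur_slope * template$depths_mm
  r <- template$well_radius
  for (i in seq_len(9)) {
    noiseless <- add_blurred_disk(noiseless, template$well_centers[i, ],
                                  r, amps[i], sigmas[i])
  }

  well_means <- vapply(seq_len(9), function(i) {
    idx <- disk_indices(template$well_centers[i, ], r, c(nr, nc))
    mean(noiseless[idx])
  }, numeric(1))

  img <- noiseless
  with_local_seed(cfg$seed, {
    if (cfg$poisson_gain > 0) {
      photons <- pmax(img, 0) / cfg$poisson_gain
      img <- matrix(stats::rpois(length(photons), photons) * cfg$poisson_gain,
                    nr, nc)
    }
    if (cfg$read_noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, cfg$read_noise_sigma),
                          nr, nc)
    }
  })
  smax <- 2^cfg$bit_depth - 1
  img <- round(pmin(pmax(img, 0), smax))

  list(
    image = intensity_image(img, bit_depth = cfg$bit_depth,
                            source_id = "synthetic"),
    ground_truth = structure(
      list(template = template, well_means = well_means,
           noiseless = noiseless, config = cfg),
      class = "phantom_ground_truth")
  )
}

check_template_in_frame <- function(template, shape) {
  r14 <- 1.4 * template$well_radius
  pts <- rbind(template$well_centers, matrix(template$b2_center, 1, 2))
  rad <- c(rep(r14, 9), template$b2_radius)
  # x -> column, y -> row, 0-based pixel centers
  bad <- pts[, 1] - rad < 0 | pts[, 1] + rad > shape[2] - 1 |
         pts[, 2] - rad < 0 | pts[, 2] + rad > shape[1] - 1
  if (any(bad)) {
    stop("geometry error: template (with b1 annuli) extends outside frame",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Evaluate a fixed RNG seed in a local scope, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  env <- parent.frame()
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval(substitute(expr), env)
}

# Add one depth-blurred well disk to an image, in place on a local patch.
add_blurred_disk <- function(img, center, radius, amplitude, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  half <- ceiling(radius + 4 * sigma + 2)
  cx <- center[1]; cy <- center[2]           # x = col, y = row (0-based)
  rows <- max(0, floor(cy) - half):min(nr - 1, ceiling(cy) + half)
  cols <- max(0, floor(cx) - half):min(nc - 1, ceiling(cx) + half)
  dy <- rows - cy
  dx <- cols - cx
  disk <- outer(dy^2, dx^2, "+") <= radius^2
  patch <- amplitude * disk
  if (sigma > 1e-8) {
    k <- gauss_kernel(sigma)
    patch <- conv_sep(patch, k)
  }
  img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + patch
  img
}

gauss_kernel <- function(sigma) {
  half <- max(1L, ceiling(4 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 2-D convolution with zero padding via Toeplitz matrices.
conv_sep <- function(mat, k) {
  conv_mat <- function(n, k) {
    half <- (length(k) - 1L) / 2L
    M <- matrix(0, n, n)
    for (j in seq_along(k)) {
      off <- j - 1L - half
      idx <- seq_len(n)
      src <- idx + off
      ok <- src >= 1 & src <= n
      M[cbind(idx[ok], src[ok])] <- M[cbind(idx[ok], src[ok])] + k[j]
    }
    M
  }
  Cr <- conv_mat(nrow(mat), k)
  Cc <- conv_mat(ncol(mat), k)
  Cr %*% mat %*% t(Cc)
}

# Linear (column-major) indices of pixels whose centers lie within `radius`
# of `center` (x = col, y = row, 0-based pixel centers).
disk_indices <- function(center, radius, shape) {
  nr <- shape[1]; nc <- shape[2]
  cx <- center[1]; cy <- center[2]
  rows <- max(0, floor(cy - radius)):min(nr - 1, ceiling(cy + radius))
  cols <- max(0, floor(cx - radius)):min(nc - 1, ceiling(cx + radius))
  inside <- outer((rows - cy)^2, (cols - cx)^2, "+") <= radius^2
  ridx <- matrix(rows + 1L, length(rows), length(cols))
  cidx <- matrix(cols + 1L, length(rows), length(cols), byrow = TRUE)
  as.integer(ridx[inside] + (cidx[inside] - 1L) * nr)
}

#' Synthetic system presets
#'
#' Six named configurations loosely mirroring the bit depth and sensor
#' resolution diversity of the six FMI systems the package's analysis is
#' designed for: a phone-camera system ("Mob", 8-bit) and five 16-bit
#' scientific cameras. Resolutions are scaled down by `scale` (default 4)
#' from the native sensor formats so the full suite renders at desk scale;
#' the scale is recorded in the `resolution_scale` attribute. Exposure and
#' fluence differences are folded into the peak amplitude.
#'
#' @param scale integer down-scaling factor applied to native resolutions.
#' @param seed base RNG seed; preset k uses `seed + k`.
#' @return Named list of six [synthetic_config()] objects with attribute
#'   `resolution_scale`.
#' @export
system_presets <- function(scale = 4, seed = 1L) {
  native <- list( # rows, cols of the native sensor formats
    "Mob"     = c(2448, 3264),
    "NIRF I"  = c(1200, 1600),
    "NIRF II" = c(2208, 2758),
    "Solaris" = c(2500, 2200),
    "RawFl"   = c(1024, 1024),
    "Hybrid"  = c(512, 512)
  )
  bits <- c("Mob" = 8, "NIRF I" = 16, "NIRF II" = 16,
            "Solaris" = 16, "RawFl" = 16, "Hybrid" = 16)
  presets <- lapply(seq_along(native), function(k) {
    nm <- names(native)[k]
    b <- bits[[nm]]
    # amplitudes sized to the dynamic range; the 8-bit preset keeps a
    # consumer-sensor black level (~8% of range) so background pixels stay
    # strictly positive under shot noise, and a peak short of saturation
    if (b == 8L) {
      bg <- 20; a0 <- 180; rn <- 1
    } else {
      bg <- 500; a0 <- 20000; rn <- 10
    }
    synthetic_config(
      image_shape = pmax(32L, as.integer(round(native[[nm]] / scale))),
      bit_depth = b, background_level = bg, peak_amplitude = a0,
      attenuation_mu = 1.0, blur_sigma0 = 1.0, blur_slope = 1.5,
      poisson_gain = 1.0, read_noise_sigma = rn,
      seed = as.integer(seed) + k
    )
  })
  names(presets) <- names(native)
  attr(presets, "resolution_scale") <- scale
  presets
}

#' Write a rendered phantom and its ground-truth sidecar
#'
#' Writes the image as 8/16-bit grayscale TIFF and a JSON sidecar holding the
#' pixel-space template, per-well noiseless means, seed and config echo.
#'
#' @param rendered result of [render_phantom()].
#' @param path output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(rendered, path) {
  write_image(rendered$image, path)
  gt <- rendered$ground_truth
  sidecar <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(
      template = list(
        well_centers = gt$template$well_centers,
        well_radius = gt$template$well_radius,
        depths_mm = gt$template$depths_mm,
        b2_center = gt$template$b2_center,
        b2_radius = gt$template$b2_radius
      ),
      well_means = gt$well_means,
      seed = gt$config$seed,
      config = unclass(gt$config)
    ),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
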