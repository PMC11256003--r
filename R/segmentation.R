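#' Otsu threshold
#'
#' Global threshold maximizing the between-class variance of the intensity
#' histogram, computed on a 256-bin histogram for both 8- and 16-bit data
#' (16-bit intensities are scaled into the bins for thresholding only; the
#' returned threshold is mapped back to raw counts). Ties are broken by the
#' lowest qualifying threshold.
#'
#' @param values numeric vector or matrix of intensities; at least two
#'   distinct values.
#' @param nbins number of histogram bins (default 256).
#' @return Threshold in raw counts: a pixel is foreground iff its intensity
#'   is strictly greater than the threshold.
#' @export
otsu_threshold <- function(values, nbins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("empty input", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    stop("degenerate-histogram error: constant input has no threshold",
         call. = FALSE)
  }
  # bin pixel i into 0..nbins-1 over [lo, hi]
  bin <- pmin(floor((v - lo) / (hi - lo) * nbins), nbins - 1L)
  counts <- tabulate(bin + 1L, nbins)
  p <- counts / sum(counts)
  midpoints <- lo + (seq_len(nbins) - 0.5) / nbins * (hi - lo)
  omega <- cumsum(p)                 # class-0 probability up to bin t
  mu <- cumsum(p * midpoints)        # class-0 cumulative mean mass
  mu_t <- mu[nbins]
  # between-class variance for split after bin t (t = 1..nbins-1)
  t <- seq_len(nbins - 1L)
  w0 <- omega[t]; w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[t][valid])^2 /
    (w0[valid] * w1[valid])
  best <- which.max(sigma_b)         # which.max takes the first (lowest) tie
  # threshold at the upper edge of bin `best`
  lo + best / nbins * (hi - lo)
}

#' Binarize an image by Otsu thresholding
#'
#' @param image an [intensity_image()] (or plain numeric matrix).
#' @return Logical matrix, `TRUE` where the intensity exceeds the Otsu
#'   threshold.
#' @export
binarize <- function(image) {
  v <- if (inherits(image, "intensity_image")) image$values else image
  v > otsu_threshold(v)
}

#' Detect circles in a binary mask
#'
#' Circular-Hough-style detection: edge pixels of the mask vote for circle
#' centers at each candidate radius; candidate centers are scored by the
#' fraction of the circle perimeter supported by votes, and non-maximum
#' suppression removes circles whose centers lie within `rmin` of a stronger
#' circle. Centers are refined to subpixel accuracy by averaging the raw
#' (unrounded) votes near the winning accumulator cell.
#'
#' @param mask logical matrix (e.g. from [binarize()]).
#' @param radius_range numeric `c(rmin, rmax)` in pixels, `0 < rmin < rmax`.
#' @param score_min minimum perimeter-support fraction to keep a candidate.
#' @param max_circles cap on the number of returned circles.
#' @return Data frame with columns `cx`, `cy` (0-based pixel coordinates,
#'   x = column, y = row), `radius`, `score`, sorted by descending score.
#'   An empty mask yields zero rows (not an error).
#' @export
find_circles <- function(mask, radius_range, score_min = 0.3,
                         max_circles = 50L) {
  stopifnot(is.matrix(mask))
  rmin <- radius_range[1]; rmax <- radius_range[2]
  if (!(rmin > 0 && rmax > rmin)) {
    stop("radius_range must satisfy 0 < rmin < rmax", call. = FALSE)
  }
  empty <- data.frame(cx = numeric(0), cy = numeric(0),
                      radius = numeric(0), score = numeric(0))
  if (!any(mask)) return(empty)
  edge <- mask_edge(mask)
  ey <- (row(edge) - 1L)[edge]   # y = row, 0-based
  ex <- (col(edge) - 1L)[edge]
  if (length(ex) == 0L) return(empty)
  nr <- nrow(mask); nc <- ncol(mask)

  cand <- list()
  for (r in seq(ceiling(rmin), floor(rmax), by = 1)) {
    ntheta <- max(16L, ceiling(2 * pi * r))
    theta <- (seq_len(ntheta) - 1) / ntheta * 2 * pi
    # candidate centers: every edge pixel displaced inward/outward along
    # all directions (votes, unrounded)
    vx <- rep(ex, each = ntheta) + rep(r * cos(theta), times = length(ex))
    vy <- rep(ey, each = ntheta) + rep(r * sin(theta), times = length(ex))
    keep <- vx >= 0 & vx <= nc - 1 & vy >= 0 & vy <= nr - 1
    vx <- vx[keep]; vy <- vy[keep]
    if (!length(vx)) next
    ix <- round(vx); iy <- round(vy)
    lin <- iy * nc + ix + 1            # accumulator cell id
    votes <- tabulate(lin, nbins = nr * nc)
    score <- votes / ntheta
    hot <- which(score >= score_min)
    if (!length(hot)) next
    # refine: average the raw votes landing in each hot cell
    in_hot <- lin %in% hot
    if (any(in_hot)) {
      grp <- factor(lin[in_hot], levels = hot)
      cxr <- tapply(vx[in_hot], grp, mean)
      cyr <- tapply(vy[in_hot], grp, mean)
      cand[[length(cand) + 1L]] <- data.frame(
        cx = as.numeric(cxr), cy = as.numeric(cyr),
        radius = r, score = score[hot])
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score), , drop = FALSE]
  # non-maximum suppression by center distance < rmin
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kept)) {
      d2 <- (cand$cx[kept] - cand$cx[i])^2 + (cand$cy[kept] - cand$cy[i])^2
      if (any(d2 < rmin^2)) next
    }
    kept <- c(kept, i)
    if (length(kept) >= max_circles) break
  }
  out <- cand[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Boundary pixels of a binary mask (mask minus its 4-neighbour erosion).
mask_edge <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  er <- pad[2:(nr + 1L), 2:(nc + 1L)] &
        pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
        pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !er
}

#' Register the design template to detected circles
#'
#' Fits the least-squares similarity transform (scale, rotation,
#' translation) mapping template well centers onto detected circle centers.
#' The initial scale comes from the median detected radius; translation
#' hypotheses are generated from all (detection, template well) pairings and
#' scored by inlier count; the fit is then refined by iterated mutual
#' nearest-neighbor matching and a closed-form complex least-squares
#' similarity solution. The returned well set uses only transformed template
#' geometry — all nine wells are present at template positions with the
#' single transformed template radius, including wells too faint to be
#' detected.
#'
#' @param circles data frame from [find_circles()] (>= 3 rows after
#'   matching).
#' @param template a design-unit [phantom_template()].
#' @param allow_rotation if `FALSE`, the rotation is constrained to zero.
#' @param max_residual_frac registration-quality bound: RMS residual must not
#'   exceed this fraction of the template well pitch (smallest pairwise
#'   center distance, transformed).
#' @return An object of class `well_set`: fields `centers` (9 x 2, pixel),
#'   `radius`, `depths_mm`, `b2_center`, `b2_radius`, `transform`,
#'   `rms_residual`, `n_matched`.
#' @export
register_template <- function(circles, template, allow_rotation = TRUE,
                              max_residual_frac = 0.25) {
  stopifnot(inherits(template, "phantom_template"))
  if (nrow(circles) < 3L) {
    stop("registration error: need at least 3 detected circles",
         call. = FALSE)
  }
  det <- cbind(circles$cx, circles$cy)
  tpl <- template$well_centers
  s0 <- stats::median(circles$radius) / template$well_radius

  # coarse translation: try pairing every detection with every template well.
  # For a regular grid a partial detection set can be translation-ambiguous;
  # tied hypotheses are resolved by preferring the one that matches the
  # shallowest template wells (wells are ordered by depth, and shallow wells
  # are the bright ones that get detected), then by residual sum.
  best <- NULL
  tol2 <- (0.75 * s0 * template$well_radius)^2
  for (i in seq_len(nrow(det))) {
    for (j in seq_len(9)) {
      tr <- det[i, ] - s0 * tpl[j, ]
      proj <- sweep(s0 * tpl, 2, tr, "+")
      d2 <- rowSums((proj - det[nearest_rows(proj, det), , drop = FALSE])^2)
      inlier <- d2 < tol2
      cand <- list(inl = sum(inlier), depth_pref = sum(which(inlier)),
                   ss = sum(d2[inlier]),
                   transform = similarity_transform(s0, 0, tr))
      if (is.null(best) || cand$inl > best$inl ||
          (cand$inl == best$inl && cand$depth_pref < best$depth_pref) ||
          (cand$inl == best$inl && cand$depth_pref == best$depth_pref &&
           cand$ss < best$ss)) {
        best <- cand
      }
    }
  }
  t_cur <- best$transform

  # iterate mutual-NN matching and least-squares refit
  match <- NULL
  for (iter in 1:5) {
    proj <- transform_points(tpl, t_cur)
    match <- mutual_nn_match(proj, det, circles$score,
                             max_dist = 0.75 * t_cur$scale *
                               template$well_radius)
    if (nrow(match) < 3L) {
      stop("registration error: fewer than 3 circles matched to template wells",
           call. = FALSE)
    }
    t_new <- fit_similarity(tpl[match$template, , drop = FALSE],
                            det[match$detection, , drop = FALSE],
                            allow_rotation = allow_rotation)
    delta <- max(abs(t_new$translation - t_cur$translation),
                 abs(t_new$scale - t_cur$scale))
    t_cur <- t_new
    if (delta < 1e-9) break
  }

  proj <- transform_points(tpl[match$template, , drop = FALSE], t_cur)
  res <- proj - det[match$detection, , drop = FALSE]
  rms <- sqrt(mean(rowSums(res^2)))
  pitch <- min(stats::dist(transform_points(tpl, t_cur)))
  if (rms > max_residual_frac * pitch) {
    stop(sprintf(
      "registration-quality error: RMS residual %.3g px exceeds %.3g px (%.0f%% of well pitch)",
      rms, max_residual_frac * pitch, 100 * max_residual_frac), call. = FALSE)
  }

  px <- apply_transform(template, t_cur)
  structure(
    list(centers = px$well_centers, radius = px$well_radius,
         depths_mm = px$depths_mm, b2_center = px$b2_center,
         b2_radius = px$b2_radius, transform = t_cur,
         rms_residual = rms, n_matched = nrow(match)),
    class = "well_set"
  )
}

#' @export
print.well_set <- function(x, ...) {
  cat(sprintf("<well_set> 9 wells, radius %.3g px, %d matched, RMS residual %.3g px\n",
              x$radius, x$n_matched, x$rms_residual))
  invisible(x)
}

nearest_rows <- function(from, to) {
  vapply(seq_len(nrow(from)), function(i) {
    which.min((to[, 1] - from[i, 1])^2 + (to[, 2] - from[i, 2])^2)
  }, integer(1))
}

# Mutual nearest-neighbour matching between projected template wells and
# detections; conflicts resolved by detection score (deterministic).
mutual_nn_match <- function(proj, det, score, max_dist) {
  fwd <- nearest_rows(proj, det)   # template -> detection
  bwd <- nearest_rows(det, proj)   # detection -> template
  rows <- list()
  for (j in seq_len(nrow(proj))) {
    i <- fwd[j]
    if (bwd[i] != j) next
    d <- sqrt(sum((proj[j, ] - det[i, ])^2))
    if (d > max_dist) next
    rows[[length(rows) + 1L]] <- data.frame(template = j, detection = i,
                                            dist = d, score = score[i])
  }
  if (!length(rows)) {
    return(data.frame(template = integer(0), detection = integer(0),
                      dist = numeric(0), score = numeric(0)))
  }
  m <- do.call(rbind, rows)
  # if one detection is mutual-NN to two template wells keep the higher score
  m <- m[order(-m$score, m$dist), , drop = FALSE]
  m <- m[!duplicated(m$detection), , drop = FALSE]
  m[order(m$template), , drop = FALSE]
}

# Closed-form least-squares similarity fit src -> dst using the complex
# formulation: minimize sum |a z + b - w|^2 with a = s e^{i theta}.
fit_similarity <- function(src, dst, allow_rotation = TRUE) {
  z <- complex(real = src[, 1], imaginary = src[, 2])
  w <- complex(real = dst[, 1], imaginary = dst[, 2])
  zc <- z - mean(z); wc <- w - mean(w)
  if (allow_rotation) {
    a <- sum(wc * Conj(zc)) / sum(Mod(zc)^2)
  } else {
    a <- complex(real = sum(Re(wc * Conj(zc))) / sum(Mod(zc)^2))
  }
  s <- Mod(a)
  if (s <= 0) stop("registration error: degenerate similarity fit",
                   call. = FALSE)
  b <- mean(w) - a * mean(z)
  similarity_transform(s, Arg(a), c(Re(b), Im(b)))
}

#' Segment wells in a phantom image
#'
#' End-to-end well localization: Otsu binarization, circle detection with a
#' radius range tied to the template (template radius times the coarse scale
#' estimate times `radius_factor`), and template registration.
#'
#' @param image an [intensity_image()].
#' @param template a design-unit [phantom_template()].
#' @param radius_range optional explicit `c(rmin, rmax)` in pixels; if
#'   `NULL`, derived from the template and a whole-frame scale estimate.
#' @param radius_factor multiplicative band around the expected radius.
#' @param allow_rotation passed to [register_template()].
#' @return A `well_set` (see [register_template()]), with the detected
#'   circles attached as attribute `circles` and the binary mask as
#'   attribute `binary`.
#' @export
segment_wells <- function(image, template, radius_range = NULL,
                          radius_factor = c(0.6, 1.4),
                          allow_rotation = TRUE) {
  stopifnot(inherits(image, "intensity_image"))
  bin <- binarize(image)
  if (is.null(radius_range)) {
    # coarse scale estimate: template spans map into the frame like
    # frame_transform would place them
    t0 <- frame_transform(template, dim(image$values))
    r0 <- template$well_radius * t0$scale
    radius_range <- r0 * radius_factor
  }
  circles <- find_circles(bin, radius_range)
  ws <- register_template(circles, template, allow_rotation = allow_rotation)
  attr(ws, "circles") <- circles
  attr(ws, "binary") <- bin
  ws
}
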