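#' Phantom design template
#'
#' Encodes the design-space geometry of the sensitivity-versus-depth phantom
#' region: nine equally sized circular fluorescent wells buried at increasing
#' depths below the phantom surface, plus the location of the distant
#' non-fluorescent background disk (the "b2" region). Coordinates are in
#' arbitrary design units; only a fitted [similarity_transform()] maps them to
#' pixels.
#'
#' @param well_centers 9 x 2 numeric matrix of (x, y) well centers in design
#'   units.
#' @param well_radius positive well radius in design units (shared by all
#'   wells).
#' @param depths_mm numeric vector of 9 strictly increasing well depths in mm.
#' @param b2_center length-2 numeric, center of the b2 background disk.
#' @param b2_radius radius of the b2 disk; defaults to `well_radius`.
#'
#' @return An object of class `phantom_template`.
#' @seealso [default_template()], [apply_transform()], [read_template_yaml()]
#' @export
phantom_template <- function(well_centers, well_radius, depths_mm,
                             b2_center, b2_radius = well_radius) {
  well_centers <- as.matrix(well_centers)
  storage.mode(well_centers) <- "double"
  dimnames(well_centers) <- NULL
  obj <- structure(
    list(
      well_centers = well_centers,
      well_radius  = as.numeric(well_radius),
      depths_mm    = as.numeric(depths_mm),
      b2_center    = as.numeric(b2_center),
      b2_radius    = as.numeric(b2_radius)
    ),
    class = "phantom_template"
  )
  validate_template(obj)
  obj
}

validate_template <- function(x) {
  if (!is.matrix(x$well_centers) || nrow(x$well_centers) != 9L ||
      ncol(x$well_centers) != 2L) {
    stop("template must have exactly 9 well centers as a 9 x 2 matrix",
         call. = FALSE)
  }
  if (length(x$depths_mm) != 9L) {
    stop("template must have exactly 9 well depths", call. = FALSE)
  }
  if (any(x$depths_mm <= 0)) stop("all depths must be > 0", call. = FALSE)
  if (any(diff(x$depths_mm) <= 0)) {
    stop("depths must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(x$well_radius) || x$well_radius <= 0) {
    stop("well_radius must be > 0", call. = FALSE)
  }
  d <- as.matrix(stats::dist(x$well_centers))
  if (any(d[upper.tri(d)] <= 2 * x$well_radius)) {
    stop("wells overlap: pairwise center distance must exceed 2 * well_radius",
         call. = FALSE)
  }
  db2 <- sqrt(colSums((t(x$well_centers) - x$b2_center)^2))
  if (any(db2 <= 2.4 * x$well_radius)) {
    stop("b2 center too close to a well: must exceed 2.4 * well_radius ",
         "so b2 never intersects a b1 annulus", call. = FALSE)
  }
  invisible(x)
}

#' Default sensitivity-versus-depth template
#'
#' A 3 x 3 grid of nine wells of unit radius at a pitch of four radii,
#' row-major order matching increasing depth (0.2 to 3.0 mm).  The b2
#' background disk sits two well-pitches beyond the right edge of the grid,
#' level with the middle row. The grid pitch and b2 offset are stand-ins for
#' the physical phantom drawing and can be overridden via a YAML template.
#'
#' @return A [phantom_template()].
#' @export
#' @examples
#' tpl <- default_template()
#' tpl$depths_mm
default_template <- function() {
  pitch <- 4
  g <- expand.grid(col = 0:2, row = 0:2)
  centers <- cbind(x = g$col * pitch, y = g$row * pitch)
  phantom_template(
    well_centers = centers,
    well_radius  = 1,
    depths_mm    = c(0.2, 0.4, 0.6, 0.8, 1.0, 1.33, 1.66, 2.0, 3.0),
    b2_center    = c(2 * pitch + 2 * pitch, pitch),
    b2_radius    = 1
  )
}

#' @export
print.phantom_template <- function(x, ...) {
  cat("<phantom_template>: 9 wells, radius", format(x$well_radius),
      "design units\n")
  cat("  depths [mm]:", paste(format(x$depths_mm), collapse = ", "), "\n")
  cat("  b2 center: (", paste(format(x$b2_center), collapse = ", "),
      "), radius ", format(x$b2_radius), "\n", sep = "")
  invisible(x)
}

#' Similarity transform (scale, rotation, translation)
#'
#' Maps design-unit coordinates into pixel space: `p = s * R(theta) %*% x + t`.
#'
#' @param scale positive unitless scale factor.
#' @param rotation rotation angle in radians (counter-clockwise).
#' @param translation length-2 numeric pixel offset.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0,
                                 translation = c(0, 0)) {
  if (!is.finite(scale) || scale <= 0) {
    stop("invalid transform: scale must be > 0", call. = FALSE)
  }
  structure(
    list(scale = as.numeric(scale), rotation = as.numeric(rotation),
         translation = as.numeric(translation)),
    class = "similarity_transform"
  )
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.6g, rotation %.6g rad, translation (%.6g, %.6g)\n",
              x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

#' Invert a similarity transform
#'
#' @param t a [similarity_transform()].
#' @return The inverse transform; applying both in sequence recovers input
#'   coordinates to floating-point precision.
#' @export
transform_inverse <- function(t) {
  stopifnot(inherits(t, "similarity_transform"))
  s <- 1 / t$scale
  th <- -t$rotation
  R <- rotation_matrix(th)
  similarity_transform(s, th, as.numeric(-s * R %*% t$translation))
}

rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Apply a similarity transform to points
#'
#' @param points n x 2 matrix (or length-2 vector) of coordinates.
#' @param t a [similarity_transform()].
#' @return Transformed coordinates, same shape as the input.
#' @export
transform_points <- function(points, t) {
  stopifnot(inherits(t, "similarity_transform"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 2) else as.matrix(points)
  out <- t$scale * p %*% t(rotation_matrix(t$rotation))
  out <- sweep(out, 2, t$translation, "+")
  if (vec) as.numeric(out) else out
}

#' Map a template through a similarity transform
#'
#' Centers are rotated, scaled and translated; radii are multiplied by the
#' scale; depths are carried through unchanged.
#'
#' @param template a [phantom_template()].
#' @param t a [similarity_transform()].
#' @return A [phantom_template()] in the target (pixel) coordinate frame.
#' @export
apply_transform <- function(template, t) {
  stopifnot(inherits(template, "phantom_template"))
  stopifnot(inherits(t, "similarity_transform"))
  phantom_template(
    well_centers = transform_points(template$well_centers, t),
    well_radius  = template$well_radius * t$scale,
    depths_mm    = template$depths_mm,
    b2_center    = transform_points(template$b2_center, t),
    b2_radius    = template$b2_radius * t$scale
  )
}

#' Read / write a phantom template as YAML
#'
#' The YAML schema has keys `well_centers` (nine `[x, y]` pairs),
#' `well_radius`, `depths_mm` (nine floats), `b2_center` and `b2_radius`.
#'
#' @param path file path.
#' @return `read_template_yaml()` returns a [phantom_template()];
#'   `write_template_yaml()` returns `path` invisibly.
#' @export
read_template_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  req <- c("well_centers", "well_radius", "depths_mm", "b2_center")
  missing <- setdiff(req, names(y))
  if (length(missing)) {
    stop("template YAML missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  centers <- do.call(rbind, lapply(y$well_centers, as.numeric))
  phantom_template(
    well_centers = centers,
    well_radius  = y$well_radius,
    depths_mm    = y$depths_mm,
    b2_center    = as.numeric(y$b2_center),
    b2_radius    = if (is.null(y$b2_radius)) y$well_radius else y$b2_radius
  )
}

#' @rdname read_template_yaml
#' @param template a [phantom_template()].
#' @export
write_template_yaml <- function(template, path) {
  stopifnot(inherits(template, "phantom_template"))
  y <- list(
    well_centers = lapply(seq_len(9), function(i)
      as.numeric(template$well_centers[i, ])),
    well_radius = template$well_radius,
    depths_mm   = template$depths_mm,
    b2_center   = template$b2_center,
    b2_radius   = template$b2_radius
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
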