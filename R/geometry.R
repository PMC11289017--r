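#' Screen geometry for pixel/visual-angle conversions
#'
#' Describes a flat screen viewed from a fixed distance. All gaze-quality
#' metrics in this package are expressed in degrees of visual angle; this
#' object carries everything needed to convert screen pixels to angles.
#'
#' Pixels are assumed square: `width_mm / height_mm` must equal
#' `width_px / height_px` within 0.1%.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param width_mm,height_mm Physical screen size in millimetres.
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#' @return An object of class `screen_geometry`.
#' @seealso [screen_from_diagonal()], [default_screen()]
#' @export
screen_geometry <- function(width_px, height_px, width_mm, height_mm,
                            viewing_distance_mm) {
  vals <- c(width_px = width_px, height_px = height_px, width_mm = width_mm,
            height_mm = height_mm, viewing_distance_mm = viewing_distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen geometry fields must be finite and > 0", call. = FALSE)
  }
  aspect_px <- width_px / height_px
  aspect_mm <- width_mm / height_mm
  if (abs(aspect_mm / aspect_px - 1) > 1e-3) {
    stop("non-square pixels: width_mm/height_mm must match width_px/height_px ",
         "within 0.1%", call. = FALSE)
  }
  structure(as.list(vals), class = "screen_geometry")
}

#' Build a screen geometry from a diagonal size
#'
#' Physical width and height are split from the diagonal in proportion to the
#' pixel resolution (square pixels), i.e.
#' `width_mm = diagonal_mm * width_px / sqrt(width_px^2 + height_px^2)`.
#'
#' @param diagonal_mm Physical diagonal in millimetres (15 inches = 381 mm).
#' @param width_px,height_px Screen resolution in pixels.
#' @param distance_mm Viewing distance in millimetres.
#' @return A `screen_geometry`.
#' @examples
#' screen_from_diagonal(381, 1440, 900, 600)
#' @export
screen_from_diagonal <- function(diagonal_mm, width_px, height_px, distance_mm) {
  args <- c(diagonal_mm, width_px, height_px, distance_mm)
  if (any(!is.finite(args)) || any(args <= 0)) {
    stop("all arguments must be finite and > 0", call. = FALSE)
  }
  diag_px <- sqrt(width_px^2 + height_px^2)
  screen_geometry(width_px, height_px,
                  width_mm = diagonal_mm * width_px / diag_px,
                  height_mm = diagonal_mm * height_px / diag_px,
                  viewing_distance_mm = distance_mm)
}

#' Default screen preset
#'
#' 15-inch (381 mm diagonal) screen at 1440 x 900 pixels viewed from 600 mm,
#' the geometry under which all shipped defaults are calibrated.
#'
#' @return A `screen_geometry`.
#' @export
default_screen <- function() {
  screen_from_diagonal(381, 1440, 900, 600)
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("screen_geometry: %d x %d px, %.1f x %.1f mm, viewed at %.0f mm\n",
              x$width_px, x$height_px, x$width_mm, x$height_mm,
              x$viewing_distance_mm))
  invisible(x)
}

as_xy_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 2) stop("point matrix must have two columns", call. = FALSE)
    return(p)
  }
  if (length(p) == 2) return(matrix(as.numeric(p), ncol = 2))
  stop("points must be a length-2 vector or an n x 2 matrix", call. = FALSE)
}

#' Convert pixel coordinates to degrees of visual angle
#'
#' Per-axis signed angle about the screen centre:
#' `deg_x = atan((x - width_px/2) * pitch / D) * 180/pi` with
#' `pitch = width_mm/width_px` and `D` the viewing distance; analogously for
#' y. The pixel convention (origin top-left, y growing downward) is inherited,
#' so positive `deg_y` points down. Off-screen points are extrapolated.
#'
#' @param p Length-2 vector `c(x, y)` in pixels, or an n x 2 matrix.
#' @param geom A [screen_geometry()].
#' @return Degrees, same shape as the input.
#' @export
px_to_deg <- function(p, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  m <- as_xy_matrix(p)
  pitch_x <- geom$width_mm / geom$width_px
  pitch_y <- geom$height_mm / geom$height_px
  d <- geom$viewing_distance_mm
  out <- cbind(atan((m[, 1] - geom$width_px / 2) * pitch_x / d),
               atan((m[, 2] - geom$height_px / 2) * pitch_y / d)) * 180 / pi
  if (!is.matrix(p)) out <- drop(out)
  out
}

#' Convert degrees of visual angle to pixel coordinates
#'
#' Exact inverse of [px_to_deg()] on the same geometry.
#'
#' @inheritParams px_to_deg
#' @param p Length-2 vector `c(deg_x, deg_y)`, or an n x 2 matrix.
#' @export
deg_to_px <- function(p, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  m <- as_xy_matrix(p)
  pitch_x <- geom$width_mm / geom$width_px
  pitch_y <- geom$height_mm / geom$height_px
  d <- geom$viewing_distance_mm
  out <- cbind(geom$width_px / 2 + d * tan(m[, 1] * pi / 180) / pitch_x,
               geom$height_px / 2 + d * tan(m[, 2] * pi / 180) / pitch_y)
  if (!is.matrix(p)) out <- drop(out)
  out
}

#' Angular distance between two on-screen points
#'
#' Euclidean norm of the per-axis visual-angle difference between two pixel
#' positions; the distance measure behind every accuracy value in the package.
#'
#' @param a,b Pixel positions: length-2 vectors or n x 2 matrices.
#' @param geom A [screen_geometry()].
#' @return Non-negative angular distance(s) in degrees.
#' @export
angular_distance <- function(a, b, geom) {
  da <- px_to_deg(as_xy_matrix(a), geom)
  db <- px_to_deg(as_xy_matrix(b), geom)
  out <- sqrt(rowSums((da - db)^2))
  if (!is.matrix(a) && !is.matrix(b)) out <- drop(out)
  out
}
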