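#' Screen model for angle-pixel conversion
#'
#' Describes the display and viewing geometry on which all visual-angle to
#' pixel conversions rest: pixel resolution, physical panel size, and the
#' observer's viewing distance. The horizontal pixel density
#' (`width_px / physical_width_cm`) is the reference density for every
#' conversion; on square-pixel monitors the choice of axis is immaterial, and
#' a sanity check flags panels whose horizontal and vertical densities differ
#' by more than 20%.
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param physical_width_cm,physical_height_cm Physical panel size in cm.
#' @param viewing_distance_cm Eye-to-screen distance in cm.
#' @param check_square_pixels If `TRUE` (default), error when the horizontal
#'   and vertical pixel densities differ by more than 20%.
#'
#' @return An object of class `screen_model`.
#' @examples
#' scr <- screen_model(1920, 1080, 50.92, 28.64, 57)
#' pixels_per_degree(scr)
#' @export
screen_model <- function(width_px, height_px, physical_width_cm,
                         physical_height_cm, viewing_distance_cm,
                         check_square_pixels = TRUE) {
  vals <- c(width_px = width_px, height_px = height_px,
            physical_width_cm = physical_width_cm,
            physical_height_cm = physical_height_cm,
            viewing_distance_cm = viewing_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid screen model: all fields must be finite and strictly positive",
         call. = FALSE)
  }
  dens_x <- width_px / physical_width_cm
  dens_y <- height_px / physical_height_cm
  if (check_square_pixels && abs(dens_x / dens_y - 1) > 0.2) {
    stop("invalid screen model: horizontal and vertical pixel densities ",
         "differ by more than 20% (set check_square_pixels = FALSE to override)",
         call. = FALSE)
  }
  structure(as.list(vals), class = "screen_model")
}

#' @describeIn screen_model Convenience constructor from a diagonal size in
#'   inches plus an aspect ratio (defaults to the common 16:9 panel).
#' @param diagonal_inches Panel diagonal in inches.
#' @param aspect Width:height aspect ratio as a length-2 numeric.
#' @export
screen_model_from_diagonal <- function(width_px, height_px, diagonal_inches,
                                       viewing_distance_cm,
                                       aspect = c(16, 9), ...) {
  stopifnot(length(aspect) == 2, all(aspect > 0))
  diag_cm <- diagonal_inches * 2.54
  unit <- diag_cm / sqrt(sum(aspect^2))
  screen_model(width_px, height_px,
               physical_width_cm = unit * aspect[1],
               physical_height_cm = unit * aspect[2],
               viewing_distance_cm = viewing_distance_cm, ...)
}

#' @export
print.screen_model <- function(x, ...) {
  cat(sprintf("<screen_model> %d x %d px, %.2f x %.2f cm, viewed at %.1f cm (%.2f px/deg)\n",
              x$width_px, x$height_px, x$physical_width_cm,
              x$physical_height_cm, x$viewing_distance_cm,
              pixels_per_degree(x)))
  invisible(x)
}

#' Pixels subtended by one degree of visual angle
#'
#' The on-screen extent of 1 degree at the model's viewing distance,
#' `2 * d * tan(0.5 deg)` cm converted to pixels via the horizontal pixel
#' density. The full tangent is used throughout; no small-angle approximation.
#'
#' @param screen A [screen_model()].
#' @return Pixels per degree (scalar).
#' @export
pixels_per_degree <- function(screen) {
  stopifnot(inherits(screen, "screen_model"))
  2 * screen$viewing_distance_cm * tan(0.5 * pi / 180) *
    (screen$width_px / screen$physical_width_cm)
}

#' Aperture diameter in pixels for a visual angle
#'
#' Projects a centrally-viewed visual angle onto the screen plane:
#' `2 * d * tan(angle/2)` cm, converted to pixels via the horizontal pixel
#' density. This is the moving-window aperture size for a gaze-contingent
#' condition (5 degrees for parafoveal+foveal viewing, 2 degrees for
#' foveal-only viewing), and is strictly increasing in both the angle and
#' the viewing distance.
#'
#' @inheritParams pixels_per_degree
#' @param angle_deg Visual angle in degrees; must be non-negative.
#' @return Aperture diameter in pixels.
#' @examples
#' scr <- screen_model(1920, 1080, 50.92, 28.64, 57)
#' aperture_diameter_px(scr, 2)  # foveal window, ~75 px
#' @export
aperture_diameter_px <- function(screen, angle_deg) {
  stopifnot(inherits(screen, "screen_model"))
  if (any(!is.finite(angle_deg)) || any(angle_deg < 0)) {
    stop("angle_deg must be non-negative and finite", call. = FALSE)
  }
  2 * screen$viewing_distance_cm * tan(angle_deg / 2 * pi / 180) *
    (screen$width_px / screen$physical_width_cm)
}

#' Aperture specification
#'
#' Couples a visual angle with its pixel diameter on a given screen, for use
#' with [within_window()].
#'
#' @inheritParams aperture_diameter_px
#' @return An object of class `aperture_spec` with fields `angle_deg` and
#'   `diameter_px`.
#' @export
aperture_spec <- function(screen, angle_deg) {
  structure(list(angle_deg = angle_deg,
                 diameter_px = aperture_diameter_px(screen, angle_deg)),
            class = "aperture_spec")
}

#' Is a gaze sample inside the moving-window aperture?
#'
#' Offline replay of the gaze-contingent mask: a point of the stimulus was
#' visible at a given sample iff its Euclidean distance from the gaze
#' position did not exceed the aperture radius. The boundary is inclusive.
#'
#' @param gaze_xy,stimulus_xy Length-2 numeric pixel coordinates, or
#'   two-column matrices of coordinates (recycled row-wise against each
#'   other).
#' @param aperture An [aperture_spec()].
#' @return Logical.
#' @export
within_window <- function(gaze_xy, stimulus_xy, aperture) {
  stopifnot(inherits(aperture, "aperture_spec"))
  g <- matrix(as.numeric(gaze_xy), ncol = 2)
  s <- matrix(as.numeric(stimulus_xy), ncol = 2)
  if (!all(is.finite(g)) || !all(is.finite(s))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  d <- sqrt((g[, 1] - s[, 1])^2 + (g[, 2] - s[, 2])^2)
  # sub-nanopixel slack keeps the inclusive boundary robust to rounding
  d <= aperture$diameter_px / 2 + 1e-9
}
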