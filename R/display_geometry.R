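# Geometry of a flat panel viewed from the fly's position: perspective
# projection between visual angles (azimuth/elevation) and physical screen
# coordinates. Angles are degrees at every interface; radians only inside.

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Flat-display geometry as seen from the fly
#'
#' Describes the physical panel, its pixel grid, and the viewing distance of
#' the tethered fly. The defaults describe a 7-inch 1024 x 600 tablet panel
#' (151.8 x 83.4 mm active area) viewed from 35 mm, which subtends roughly
#' 130 deg of azimuth and 100 deg of elevation at the fly's position.
#'
#' @param physical_width,physical_height Active panel size in mm.
#' @param px_width,px_height Panel resolution in pixels.
#' @param viewer_distance Distance from the fly to the panel center, mm.
#' @param refresh_rate Display refresh rate in Hz.
#'
#' @return An object of class `display_geometry`.
#' @examples
#' geom <- display_geometry()
#' visible_field(geom)
#' @export
display_geometry <- function(physical_width = 151.8, physical_height = 83.4,
                             px_width = 1024L, px_height = 600L,
                             viewer_distance = 35, refresh_rate = 60) {
  stopifnot(
    physical_width > 0, physical_height > 0,
    px_width >= 1, px_height >= 1,
    viewer_distance > 0, refresh_rate > 0
  )
  structure(
    list(
      physical_width = physical_width, physical_height = physical_height,
      px_width = as.integer(px_width), px_height = as.integer(px_height),
      viewer_distance = viewer_distance, refresh_rate = refresh_rate
    ),
    class = "display_geometry"
  )
}

#' @export
print.display_geometry <- function(x, ...) {
  fov <- visible_field(x)
  cat(sprintf(
    "<display_geometry> %.1f x %.1f mm (%d x %d px), viewed from %.1f mm @ %g Hz\n",
    x$physical_width, x$physical_height, x$px_width, x$px_height,
    x$viewer_distance, x$refresh_rate
  ))
  cat(sprintf("  field of view: %.1f deg azimuth x %.1f deg elevation\n",
              fov[["azimuth"]], fov[["elevation"]]))
  invisible(x)
}

#' Virtual cylinder carrying the stimulus pattern
#'
#' The stimulus lives on a virtual cylinder centered on the fly (default
#' diameter 305 mm, matching a typical LED arena); the panel shows its
#' perspective projection. Because the fly sits on the cylinder axis, the
#' projected image depends only on the angular layout of the segments, never
#' on the cylinder diameter.
#'
#' @param diameter Cylinder diameter in mm.
#' @param segments Data frame with columns `azimuth_start`, `azimuth_end`
#'   (degrees, non-overlapping) and `luminance` (in `[0, 1]`).
#' @return An object of class `virtual_cylinder`.
#' @export
virtual_cylinder <- function(diameter = 305, segments = NULL) {
  stopifnot(diameter > 0)
  if (is.null(segments)) {
    segments <- tibble::tibble(azimuth_start = numeric(), azimuth_end = numeric(),
                               luminance = numeric())
  }
  stopifnot(all(c("azimuth_start", "azimuth_end", "luminance") %in% names(segments)))
  if (nrow(segments)) {
    if (any(segments$azimuth_end <= segments$azimuth_start))
      stop("virtual_cylinder(): each segment needs azimuth_end > azimuth_start")
    if (any(segments$luminance < 0 | segments$luminance > 1))
      stop("virtual_cylinder(): luminance must lie in [0, 1]")
    o <- order(segments$azimuth_start)
    s <- segments[o, ]
    if (nrow(s) > 1 && any(s$azimuth_start[-1] < s$azimuth_end[-nrow(s)]))
      stop("virtual_cylinder(): segments overlap in azimuth")
  }
  structure(list(diameter = diameter, segments = tibble::as_tibble(segments)),
            class = "virtual_cylinder")
}

#' Project a visual azimuth onto the flat screen
#'
#' Maps an azimuth angle at the fly's position to the horizontal physical
#' offset (mm from screen center) where a ray through that azimuth meets the
#' panel: `x = d * tan(azimuth)`. Positive azimuth is to the fly's right and
#' maps to positive offset. Only angles strictly inside (-90, 90) deg have a
#' projection onto the screen plane.
#'
#' @param azimuth Azimuth in degrees, `|azimuth| < 90`. Vectorized.
#' @param geom A [display_geometry()].
#' @return Offset(s) from screen center in mm.
#' @examples
#' azimuth_to_screen_x(45, display_geometry())  # 35 mm
#' @export
azimuth_to_screen_x <- function(azimuth, geom = display_geometry()) {
  if (any(!is.finite(azimuth)) || any(abs(azimuth) >= 90))
    stop("azimuth_to_screen_x(): |azimuth| must be < 90 deg (projection onto the screen plane is undefined behind it)")
  geom$viewer_distance * tan(deg2rad(azimuth))
}

#' Visual azimuth of a horizontal screen position
#'
#' Exact inverse of [azimuth_to_screen_x()]: `atan(x / d)`, in degrees.
#'
#' @param x Horizontal offset(s) from screen center, mm. Any finite value.
#' @inheritParams azimuth_to_screen_x
#' @return Azimuth in degrees, in (-90, 90).
#' @export
screen_x_to_azimuth <- function(x, geom = display_geometry()) {
  rad2deg(atan(x / geom$viewer_distance))
}

#' Physical on-screen width of an azimuthal arc
#'
#' Width in mm of the screen region spanned by `[az_lo, az_hi]` degrees of
#' azimuth: `d * (tan(az_hi) - tan(az_lo))`. For a fixed angular span the
#' physical width grows toward the screen edges — the view-angle correction
#' that keeps every grating bar an equal angular size for the fly.
#'
#' @param az_lo,az_hi Arc bounds in degrees, `-90 < az_lo < az_hi < 90`.
#' @inheritParams azimuth_to_screen_x
#' @return Width in mm (strictly positive).
#' @export
arc_screen_width <- function(az_lo, az_hi, geom = display_geometry()) {
  if (any(az_hi <= az_lo)) stop("arc_screen_width(): need az_hi > az_lo")
  azimuth_to_screen_x(az_hi, geom) - azimuth_to_screen_x(az_lo, geom)
}

#' Field of view of the panel from the fly's position
#'
#' @inheritParams azimuth_to_screen_x
#' @return Named numeric vector: `azimuth` and `elevation` spans in degrees,
#'   each `2 * atan(half extent / viewing distance)`.
#' @export
visible_field <- function(geom = display_geometry()) {
  c(
    azimuth   = 2 * rad2deg(atan(geom$physical_width  / 2 / geom$viewer_distance)),
    elevation = 2 * rad2deg(atan(geom$physical_height / 2 / geom$viewer_distance))
  )
}

#' Physical x offsets of pixel-column centers
#'
#' @inheritParams azimuth_to_screen_x
#' @return Numeric vector of length `px_width`: mm from screen center, with
#'   constant pixel pitch `physical_width / px_width`.
#' @export
pixel_centers_x <- function(geom = display_geometry()) {
  pitch <- geom$physical_width / geom$px_width
  (seq_len(geom$px_width) - 0.5) * pitch - geom$physical_width / 2
}
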