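#' Four-panel arena geometry
#'
#' Describes the physical geometry of a four-sided flat-panel arena used to
#' emulate a cylindrical optomotor drum, together with the viewer's position
#' inside it. All angular computations in the package derive from this
#' object.
#'
#' Coordinate conventions: the origin sits at the centre of the square
#' footprint, `z = 0` at the bottom edge of the panels. Panel `k` (0-based)
#' has its centre at azimuth `90 * k` degrees; azimuth increases
#' counter-clockwise viewed from above, with azimuth 0 at the centre of
#' panel 0. Elevation is measured from the viewer's eye height. Pixels are
#' addressed 0-based with pixel centres at half-integer offsets; row 0 is
#' the top of the panel.
#'
#' @param wall_width Width of each wall in cm (also the footprint side).
#' @param wall_height Height of each wall in cm.
#' @param panel_px_w,panel_px_h Panel resolution in pixels.
#' @param viewer_xy Viewer position in the footprint plane, cm from centre;
#'   must lie strictly inside the footprint.
#' @param viewer_eye_height Eye height above the panel bottom edge, cm.
#'   Defaults to mid-height; the animal's true eye height is rarely known,
#'   so it is left configurable.
#' @param n_walls Number of walls; only 4 is supported.
#'
#' @return An object of class `arena_geometry`.
#' @examples
#' geom <- arena_geometry()
#' wall_subtense(geom)
#' @export
arena_geometry <- function(wall_width = 38.5, wall_height = 30.0,
                           panel_px_w = 192L, panel_px_h = 148L,
                           viewer_xy = c(0, 0),
                           viewer_eye_height = wall_height / 2,
                           n_walls = 4L) {
  if (!is_scalar_number(wall_width) || wall_width <= 0)
    stop_polardrum("`wall_width` must be a positive number (cm)", "invalid_geometry")
  if (!is_scalar_number(wall_height) || wall_height <= 0)
    stop_polardrum("`wall_height` must be a positive number (cm)", "invalid_geometry")
  if (n_walls != 4L)
    stop_polardrum("only four-walled arenas are supported (`n_walls` = 4)", "invalid_geometry")
  if (panel_px_w < 1 || panel_px_h < 1)
    stop_polardrum("panel resolution must be at least 1x1 px", "invalid_geometry")
  if (length(viewer_xy) != 2L || any(abs(viewer_xy) >= wall_width / 2))
    stop_polardrum("viewer must lie strictly inside the arena footprint", "invalid_geometry")
  if (!is_scalar_number(viewer_eye_height) || viewer_eye_height <= 0 ||
      viewer_eye_height >= wall_height)
    stop_polardrum("`viewer_eye_height` must lie within the wall height", "invalid_geometry")
  structure(
    list(
      wall_width = wall_width, wall_height = wall_height,
      panel_px_w = as.integer(panel_px_w), panel_px_h = as.integer(panel_px_h),
      viewer_xy = as.numeric(viewer_xy),
      viewer_eye_height = viewer_eye_height,
      n_walls = 4L
    ),
    class = "arena_geometry"
  )
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf(
    "<arena_geometry> 4 walls %.1f x %.1f cm, %d x %d px, viewer (%.2f, %.2f) cm, eye %.2f cm\n",
    x$wall_width, x$wall_height, x$panel_px_w, x$panel_px_h,
    x$viewer_xy[1], x$viewer_xy[2], x$viewer_eye_height
  ))
  invisible(x)
}

# World coordinates (cm) of fractional pixel positions on a panel.
# px, py are 0-based continuous pixel coordinates (centres at half-integers
# are produced by px + 0.5 upstream; here px is used as-is).
panel_point_world <- function(panel, px, py, geom) {
  w <- geom$wall_width; h <- geom$wall_height
  d <- w / 2
  u <- -w / 2 + px * (w / geom$panel_px_w)   # lateral offset, increases with azimuth
  z <- h - py * (h / geom$panel_px_h)        # py = 0 is the top edge
  ang <- deg2rad(90 * panel)
  list(
    x = cos(ang) * d - sin(ang) * u,
    y = sin(ang) * d + cos(ang) * u,
    z = z
  )
}

#' Map panel pixels to viewing directions
#'
#' Casts a ray from the viewer through the physical centre of each listed
#' pixel and returns its azimuth/elevation. The map is continuous across
#' panel seams, which is what makes the four flat panels act as a single
#' virtual drum.
#'
#' @param pixels A data frame with columns `panel` (0-based wall index),
#'   `px`, `py` (0-based pixel indices; fractional values address sub-pixel
#'   positions).
#' @param geom An [arena_geometry()].
#' @return The input as a tibble with `azimuth` (degrees in `[0, 360)`) and
#'   `elevation` (degrees) columns added.
#' @seealso [direction_to_panel_pixel()] for the inverse map.
#' @export
panel_pixel_to_direction <- function(pixels, geom) {
  stopifnot(inherits(geom, "arena_geometry"))
  pixels <- tibble::as_tibble(pixels)
  if (!all(c("panel", "px", "py") %in% names(pixels)))
    stop_polardrum("`pixels` needs columns panel, px, py", "bounds_error")
  if (any(pixels$panel < 0 | pixels$panel >= geom$n_walls))
    stop_polardrum("panel index out of range [0, 4)", "bounds_error")
  # pixel centres sit at half-integer physical offsets, so continuous
  # coordinates are valid on [-0.5, size - 0.5]
  if (any(pixels$px < -0.5 | pixels$px > geom$panel_px_w - 0.5 |
          pixels$py < -0.5 | pixels$py > geom$panel_px_h - 0.5))
    stop_polardrum(
      "pixel coordinates outside panel bounds (centres live in [-0.5, size - 0.5])",
      "bounds_error")
  p <- panel_point_world(pixels$panel, pixels$px + 0.5, pixels$py + 0.5, geom)
  dx <- p$x - geom$viewer_xy[1]
  dy <- p$y - geom$viewer_xy[2]
  dz <- p$z - geom$viewer_eye_height
  dplyr::mutate(
    pixels,
    azimuth = wrap360(rad2deg(atan2(dy, dx))),
    elevation = rad2deg(atan2(dz, sqrt(dx^2 + dy^2)))
  )
}

#' Map viewing directions back to panel pixels
#'
#' Inverse of [panel_pixel_to_direction()]: intersects each viewing ray with
#' the four wall planes and reports which panel (if any) it hits, with
#' continuous (sub-pixel) pixel coordinates. Directions passing above or
#' below the walls' vertical extent return `NA` rather than an error.
#'
#' @param directions A data frame with columns `azimuth`, `elevation`
#'   (degrees).
#' @inheritParams panel_pixel_to_direction
#' @return The input as a tibble with `panel`, `px`, `py` columns added
#'   (`NA` where the ray misses all panels).
#' @export
direction_to_panel_pixel <- function(directions, geom) {
  stopifnot(inherits(geom, "arena_geometry"))
  directions <- tibble::as_tibble(directions)
  if (!all(c("azimuth", "elevation") %in% names(directions)))
    stop_polardrum("`directions` needs columns azimuth, elevation", "bounds_error")
  az <- deg2rad(directions$azimuth)
  el <- deg2rad(directions$elevation)
  Dx <- cos(az) * cos(el); Dy <- sin(az) * cos(el); Dz <- sin(el)
  w <- geom$wall_width; h <- geom$wall_height; d <- w / 2
  W <- geom$panel_px_w; H <- geom$panel_px_h
  vx <- geom$viewer_xy[1]; vy <- geom$viewer_xy[2]; vz <- geom$viewer_eye_height
  n <- length(az)
  panel <- rep(NA_integer_, n); px <- rep(NA_real_, n); py <- rep(NA_real_, n)
  for (k in 0:3) {
    ang <- deg2rad(90 * k)
    # rotate viewer and direction into the panel frame (panel plane x = d)
    rvx <- cos(ang) * vx + sin(ang) * vy
    rvy <- -sin(ang) * vx + cos(ang) * vy
    rDx <- cos(ang) * Dx + sin(ang) * Dy
    rDy <- -sin(ang) * Dx + cos(ang) * Dy
    ok <- is.na(panel) & rDx > 1e-12
    t <- (d - rvx) / rDx
    u <- rvy + t * rDy
    z <- vz + t * Dz
    eps <- 1e-9 * max(w, h)   # absorb round-off at wall edges
    hit <- ok & t > 0 & u >= -w / 2 - eps & u <= w / 2 + eps &
      z >= -eps & z <= h + eps
    panel[hit] <- k
    px[hit] <- (u[hit] + w / 2) / w * W - 0.5
    py[hit] <- (h - z[hit]) / h * H - 0.5
  }
  dplyr::mutate(directions, panel = panel, px = px, py = py)
}

#' Angular subtense of one wall
#'
#' Horizontal and vertical visual angle of a single wall seen by a central
#' viewer. Horizontally a wall of width equal to the footprint side always
#' subtends exactly 90 degrees; vertically the subtense depends on eye
#' height.
#'
#' @inheritParams panel_pixel_to_direction
#' @param distance Viewer-to-wall-plane distance in cm. Defaults to
#'   `wall_width / 2` (central viewer); override to explore other
#'   wall-width/distance combinations.
#' @return Named numeric vector `c(horizontal =, vertical =)` in degrees.
#' @export
wall_subtense <- function(geom, distance = geom$wall_width / 2) {
  stopifnot(inherits(geom, "arena_geometry"))
  if (any(geom$viewer_xy != 0))
    stop_polardrum("wall_subtense assumes a central viewer", "invalid_geometry")
  if (!is_scalar_number(distance) || distance <= 0)
    stop_polardrum("degenerate geometry: viewer-to-wall distance must be > 0",
                   "invalid_geometry")
  h_above <- geom$wall_height - geom$viewer_eye_height
  h_below <- geom$viewer_eye_height
  c(
    horizontal = 2 * rad2deg(atan((geom$wall_width / 2) / distance)),
    vertical = rad2deg(atan(h_above / distance)) + rad2deg(atan(h_below / distance))
  )
}
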