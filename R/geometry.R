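#' Fisheye projection geometry
#'
#' Describes how a hemispherical (fisheye) image maps pixels to sky
#' directions.  The projection is equidistant (equi-angular): the radial
#' pixel distance from the optical centre is proportional to the zenith
#' angle, `r = radius_px * zenith / max_zenith`.  An optional equisolid
#' model (`r = k * sin(zenith/2)`) is available for lenses known to follow
#' it.  The optical axis is assumed vertical, so the image centre looks at
#' the zenith; a 150 degree field-of-view lens sees zenith angles 0-75
#' degrees and the 75-90 degree ring is outside the image.
#'
#' @param center_row,center_col Pixel coordinates (1-based, rows increase
#'   downward) of the optical axis.
#' @param radius_px Radius in pixels from the centre to the edge of the
#'   field of view.
#' @param max_zenith Zenith angle in degrees at the field-of-view edge.
#'   Defaults to 75 (half of a 150 degree field of view).
#' @param azimuth_offset Compass azimuth in degrees of the image "up"
#'   direction (0 = north, clockwise).
#' @param projection `"equidistant"` (default) or `"equisolid"`.
#'
#' @return An object of class `fisheye_geometry`.
#' @examples
#' geom <- fisheye_geometry(center_row = 101, center_col = 101, radius_px = 100)
#' pixel_to_direction(1, 101, geom)     # top of the image -> zenith 75, az 0
#' @export
fisheye_geometry <- function(center_row, center_col, radius_px,
                             max_zenith = 75, azimuth_offset = 0,
                             projection = c("equidistant", "equisolid")) {
  projection <- match.arg(projection)
  if (!is.numeric(radius_px) || radius_px <= 0) {
    abort("`radius_px` must be a positive number.")
  }
  if (max_zenith <= 0 || max_zenith > 90) {
    abort("`max_zenith` must be in (0, 90] degrees.")
  }
  if (azimuth_offset < 0 || azimuth_offset >= 360) {
    abort("`azimuth_offset` must be in [0, 360) degrees.")
  }
  structure(
    list(center_row = center_row, center_col = center_col,
         radius_px = radius_px, max_zenith = max_zenith,
         azimuth_offset = azimuth_offset, projection = projection),
    class = "fisheye_geometry"
  )
}

#' @export
print.fisheye_geometry <- function(x, ...) {
  cat(sprintf(
    "<fisheye_geometry> centre (%g, %g), radius %g px, max zenith %g deg, az offset %g deg, %s\n",
    x$center_row, x$center_col, x$radius_px, x$max_zenith,
    x$azimuth_offset, x$projection))
  invisible(x)
}

# radial pixel distance for a zenith angle (degrees), per projection model
zenith_to_radial <- function(zenith, geometry) {
  switch(geometry$projection,
    equidistant = geometry$radius_px * zenith / geometry$max_zenith,
    equisolid = geometry$radius_px *
      sin(deg2rad(zenith) / 2) / sin(deg2rad(geometry$max_zenith) / 2)
  )
}

radial_to_zenith <- function(radial, geometry) {
  switch(geometry$projection,
    equidistant = geometry$max_zenith * radial / geometry$radius_px,
    equisolid = 2 * rad2deg(asin(pmin(
      1, radial * sin(deg2rad(geometry$max_zenith) / 2) / geometry$radius_px)))
  )
}

#' Map image pixels to sky directions
#'
#' Converts pixel coordinates to the (zenith, azimuth) direction they image,
#' under the geometry's projection model.  Azimuth follows the compass
#' convention shared by all of canopylux: 0 = north, increasing clockwise,
#' in `[0, 360)`.  The centre pixel has undefined azimuth and returns 0 by
#' convention.
#'
#' @param row,col Pixel coordinates (vectorised; 1-based).
#' @param geometry A [fisheye_geometry()].
#' @return A tibble with columns `row`, `col`, `zenith`, `azimuth` (degrees).
#' @seealso [direction_to_pixel()] for the inverse mapping.
#' @export
pixel_to_direction <- function(row, col, geometry) {
  stopifnot(inherits(geometry, "fisheye_geometry"))
  dx <- col - geometry$center_col          # image right
  dy <- geometry$center_row - row          # image up
  radial <- sqrt(dx^2 + dy^2)
  outside <- radial > geometry$radius_px + 1e-9
  if (any(outside)) {
    abort(sprintf("%d pixel(s) lie outside the field-of-view circle.",
                  sum(outside)))
  }
  zenith <- radial_to_zenith(radial, geometry)
  azimuth <- ifelse(radial == 0, 0,
                    (rad2deg(atan2(dx, dy)) + geometry$azimuth_offset) %% 360)
  tibble(row = row, col = col, zenith = zenith, azimuth = azimuth)
}

#' Map sky directions to image pixels
#'
#' Inverse of [pixel_to_direction()].  Directions beyond the field of view
#' (`zenith > max_zenith`) are an error; callers modelling beam interception
#' treat that ring as blocked instead of calling this function.
#'
#' @param zenith,azimuth Direction in degrees (vectorised); compass azimuth.
#' @inheritParams pixel_to_direction
#' @return A tibble with columns `zenith`, `azimuth`, `row`, `col`
#'   (fractional pixel coordinates).
#' @export
direction_to_pixel <- function(zenith, azimuth, geometry) {
  stopifnot(inherits(geometry, "fisheye_geometry"))
  if (any(zenith < 0 | zenith > geometry$max_zenith)) {
    abort(sprintf(
      "zenith outside field of view: max_zenith is %g degrees.",
      geometry$max_zenith))
  }
  radial <- zenith_to_radial(zenith, geometry)
  bearing <- deg2rad(azimuth - geometry$azimuth_offset)
  tibble(zenith = zenith, azimuth = azimuth,
         row = geometry$center_row - radial * cos(bearing),
         col = geometry$center_col + radial * sin(bearing))
}

# zenith/azimuth matrices for every pixel of a grid; NA outside the FOV.
# Returned as a list(zenith, azimuth, valid) of matrices, computed once per
# mask and reused by the metric and radiation code.
direction_grid <- function(dim, geometry) {
  rows <- matrix(seq_len(dim[1]), nrow = dim[1], ncol = dim[2])
  cols <- matrix(seq_len(dim[2]), nrow = dim[1], ncol = dim[2], byrow = TRUE)
  dx <- cols - geometry$center_col
  dy <- geometry$center_row - rows
  radial <- sqrt(dx^2 + dy^2)
  valid <- radial <= geometry$radius_px
  zenith <- radial_to_zenith(radial, geometry)
  azimuth <- (rad2deg(atan2(dx, dy)) + geometry$azimuth_offset) %% 360
  azimuth[radial == 0] <- 0
  zenith[!valid] <- NA_real_
  azimuth[!valid] <- NA_real_
  list(zenith = zenith, azimuth = azimuth, valid = valid)
}

# unit vectors (east, north, up) for pixel directions; used for angular
# distances to the sun without trig per timestep
direction_unit_vectors <- function(zenith, azimuth) {
  zr <- deg2rad(zenith)
  ar <- deg2rad(azimuth)
  list(e = sin(zr) * sin(ar), n = sin(zr) * cos(ar), u = cos(zr))
}
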