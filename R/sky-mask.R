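#' Binary sky/canopy mask from a hemispherical image
#'
#' A `sky_mask` holds a logical grid (`TRUE` = sky, `FALSE` = canopy,
#' `NA` = outside the field-of-view circle) together with its
#' [fisheye_geometry()].  Pixels outside the field of view never enter any
#' statistic computed downstream.
#'
#' @param grid Logical matrix; `NA` marks invalid pixels.
#' @param geometry A [fisheye_geometry()]; the field-of-view circle must fit
#'   inside the grid.
#' @param source_id Free-text identifier carried into result tables.
#' @param threshold Optional effective threshold recorded for audit.
#' @return An object of class `sky_mask`.
#' @export
sky_mask <- function(grid, geometry, source_id = "mask", threshold = NA_real_) {
  stopifnot(is.matrix(grid), is.logical(grid),
            inherits(geometry, "fisheye_geometry"))
  check_fov_fits(dim(grid), geometry)
  dg <- direction_grid(dim(grid), geometry)
  grid[!dg$valid] <- NA
  structure(
    list(grid = grid, geometry = geometry, source_id = source_id,
         threshold = threshold, directions = dg),
    class = "sky_mask"
  )
}

check_fov_fits <- function(dim, geometry) {
  g <- geometry
  if (g$center_row - g$radius_px < 0.5 || g$center_row + g$radius_px > dim[1] + 0.5 ||
      g$center_col - g$radius_px < 0.5 || g$center_col + g$radius_px > dim[2] + 0.5) {
    abort("Field-of-view circle exceeds the image bounds.")
  }
  invisible(TRUE)
}

#' @export
print.sky_mask <- function(x, ...) {
  nv <- sum(!is.na(x$grid))
  cat(sprintf(
    "<sky_mask> '%s': %d x %d px, %d valid, sky fraction %.3f%s\n",
    x$source_id, nrow(x$grid), ncol(x$grid), nv,
    mean(x$grid, na.rm = TRUE),
    if (is.na(x$threshold)) "" else sprintf(", threshold %g", x$threshold)))
  invisible(x)
}

#' Segment sky from canopy on the blue channel
#'
#' Thresholds the blue channel of an RGB hemispherical photograph: a pixel
#' is sky when its blue value is at or above the threshold.  The same fixed
#' threshold is meant to be applied identically across an image set; Otsu's
#' method is offered as an alternative and is best computed once on the
#' pooled blue histogram of the whole set (see [otsu_threshold()]) and then
#' passed as a fixed threshold.
#'
#' @param image Numeric array `H x W x 3` (RGB).  Values either in `[0, 1]`
#'   (as returned by [png::readPNG()]) or 8-bit `[0, 255]`; both are mapped
#'   to the 0-255 scale before thresholding.
#' @param geometry A [fisheye_geometry()].
#' @param mode `"fixed"` (default) or `"otsu"`.  `"otsu"` computes the
#'   threshold from this image's own blue histogram over valid pixels.
#' @param threshold Blue-channel threshold on the 0-255 scale
#'   (used when `mode = "fixed"`; default 128).
#' @param source_id Identifier recorded in the mask.
#' @return A [sky_mask()] whose `threshold` field records the effective
#'   threshold used.
#' @examples
#' geom <- fisheye_geometry(26, 26, 25)
#' img <- array(0, dim = c(51, 51, 3))
#' img[, , 3] <- 200 / 255
#' mask <- binarize_blue(img, geom, threshold = 128)
#' porosity(mask)
#' @export
binarize_blue <- function(image, geometry, mode = c("fixed", "otsu"),
                          threshold = 128, source_id = "image") {
  mode <- match.arg(mode)
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    abort("`image` must be an RGB array with three channels.")
  }
  blue <- image[, , 3]
  if (max(blue, na.rm = TRUE) <= 1) blue <- blue * 255
  if (mode == "fixed") {
    if (threshold < 0 || threshold > 255) {
      abort("`threshold` must be in [0, 255].")
    }
    thr <- threshold
  } else {
    dg <- direction_grid(dim(blue), geometry)
    thr <- otsu_threshold(list(blue[dg$valid]))
  }
  sky_mask(blue >= thr, geometry, source_id = source_id, threshold = thr)
}

#' Otsu threshold of pooled blue-channel values
#'
#' Exhaustive search over the 256 candidate 8-bit thresholds maximising the
#' between-class variance of the pooled histogram.  Pool the blue channels
#' of a whole image set here to derive one threshold applied identically to
#' every image.
#'
#' @param blues A list of numeric vectors/matrices of blue values (each on
#'   `[0, 1]` or `[0, 255]`).
#' @return The threshold on the 0-255 scale: sky is `blue >= threshold`.
#' @export
otsu_threshold <- function(blues) {
  if (!is.list(blues)) blues <- list(blues)
  v <- unlist(lapply(blues, function(b) {
    b <- as.numeric(b[!is.na(b)])
    if (length(b) && max(b) <= 1) b <- b * 255
    b
  }))
  if (!length(v)) abort("No pixel values supplied.")
  counts <- tabulate(pmin(pmax(floor(v), 0), 255) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  best_t <- 0; best_var <- -1
  for (t in 0:255) {
    w0 <- sum(p[levels < t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(levels[levels < t] * p[levels < t]) / w0
    mu1 <- sum(levels[levels >= t] * p[levels >= t]) / w1
    bv <- w0 * w1 * (mu0 - mu1)^2
    if (bv > best_var) { best_var <- bv; best_t <- t }
  }
  best_t
}

#' Read a hemispherical photograph
#'
#' Reads an 8-bit RGB PNG (or JPEG when the \pkg{jpeg} package is
#' installed) into the array layout [binarize_blue()] expects.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return Numeric array `H x W x 3` with values in `[0, 1]`.
#' @export
read_hemi_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        abort("Reading JPEG requires the 'jpeg' package.")
      }
      jpeg::readJPEG(path)
    },
    abort(sprintf("Unsupported image format '%s'; use PNG or JPEG.", ext))
  )
  if (length(dim(img)) == 2) {           # greyscale: replicate channels
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  img[, , 1:3, drop = FALSE]
}

#' Write and re-read sky masks as PNG
#'
#' Masks are stored as single-channel PNG: 0 = canopy, 255 = sky, mid-grey
#' (128) = invalid (outside the field of view).  A JSON audit record with
#' the threshold and sky fraction is written alongside.
#'
#' @param mask A [sky_mask()].
#' @param path Output PNG path; the audit record goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "sky_mask"))
  img <- matrix(128 / 255, nrow(mask$grid), ncol(mask$grid))
  img[which(mask$grid)] <- 1
  img[which(!mask$grid)] <- 0
  png::writePNG(img, path)
  audit <- list(source_id = mask$source_id, threshold = mask$threshold,
                sky_fraction = mean(mask$grid, na.rm = TRUE),
                n_valid = sum(!is.na(mask$grid)))
  jsonlite::write_json(audit, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_mask_png
#' @param geometry,source_id Passed to [sky_mask()] when re-reading.
#' @export
read_mask_png <- function(path, geometry, source_id = basename(path)) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  grid <- matrix(NA, nrow(img), ncol(img))
  grid[img > 0.75] <- TRUE
  grid[img < 0.25] <- FALSE
  audit_path <- paste0(path, ".json")
  thr <- NA_real_
  if (file.exists(audit_path)) {
    thr <- jsonlite::read_json(audit_path)$threshold %||% NA_real_
  }
  sky_mask(grid, geometry, source_id = source_id,
           threshold = suppressWarnings(as.numeric(thr)))
}
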