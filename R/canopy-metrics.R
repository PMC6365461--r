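#' Zenith-angle bands for gap-fraction analysis
#'
#' Five 13-degree-wide bands centred at zenith angles 7, 23, 38, 53 and 68
#' degrees, weighted 0.034, 0.104, 0.160, 0.218 and 0.494 — the ring
#' configuration of commercial plant canopy analyzers adapted to
#' hemispherical images.  Band membership is decided by half-open intervals
#' `[centre - width/2, centre + width/2)` on the pixel zenith angle.
#'
#' The printed weights sum to 1.010; they are used as printed by default,
#' with `normalize = TRUE` available to rescale them to sum to 1.
#'
#' @param centers Band centres in degrees.
#' @param width Band width in degrees.
#' @param weights One positive weight per band.
#' @param normalize Rescale weights to sum to 1?  Default `FALSE`.
#' @return An object of class `zenith_bands`.
#' @export
zenith_bands <- function(centers = c(7, 23, 38, 53, 68), width = 13,
                         weights = c(0.034, 0.104, 0.160, 0.218, 0.494),
                         normalize = FALSE) {
  if (length(centers) != length(weights)) {
    abort("`centers` and `weights` must have the same length.")
  }
  if (any(weights <= 0)) abort("All band weights must be positive.")
  lo <- centers - width / 2
  hi <- centers + width / 2
  if (any(head(hi, -1) > tail(lo, -1))) abort("Bands must not overlap.")
  if (normalize) weights <- weights / sum(weights)
  structure(
    list(centers = centers, width = width, weights = weights,
         lower = lo, upper = hi),
    class = "zenith_bands"
  )
}

#' @export
print.zenith_bands <- function(x, ...) {
  cat(sprintf("<zenith_bands> %d bands, width %g deg\n",
              length(x$centers), x$width))
  print(tibble(center = x$centers, lower = x$lower, upper = x$upper,
               weight = x$weights))
  invisible(x)
}

#' Canopy porosity
#'
#' Fraction of valid (inside the field of view) pixels classified as sky.
#'
#' @param mask A [sky_mask()].
#' @return A fraction in `[0, 1]`.
#' @export
porosity <- function(mask) {
  stopifnot(inherits(mask, "sky_mask"))
  n_valid <- sum(!is.na(mask$grid))
  if (n_valid == 0) abort("Mask has no valid pixels.")
  mean(mask$grid, na.rm = TRUE)
}

#' Gap fraction per zenith band
#'
#' Mean sky fraction of the valid pixels whose zenith angle falls inside
#' each band.
#'
#' @param mask A [sky_mask()].
#' @param bands A [zenith_bands()].
#' @return Numeric vector of gap fractions, one per band, named `t1..t5`.
#' @export
band_gap_fractions <- function(mask, bands = zenith_bands()) {
  stopifnot(inherits(mask, "sky_mask"), inherits(bands, "zenith_bands"))
  z <- mask$directions$zenith
  vapply(seq_along(bands$centers), function(i) {
    sel <- !is.na(z) & z >= bands$lower[i] & z < bands$upper[i]
    if (!any(sel)) {
      abort(sprintf(
        "Band %d (%g-%g deg) contains no valid pixels; geometry too small.",
        i, bands$lower[i], bands$upper[i]))
    }
    mean(mask$grid[sel])
  }, numeric(1)) |>
    setNames(paste0("t", seq_along(bands$centers)))
}

band_pixel_counts <- function(mask, bands = zenith_bands()) {
  z <- mask$directions$zenith
  vapply(seq_along(bands$centers), function(i) {
    sum(!is.na(z) & z >= bands$lower[i] & z < bands$upper[i])
  }, integer(1))
}

#' Leaf area index from band gap fractions
#'
#' Five-ring gap-fraction inversion
#' `LAI = 2 * sum_i W_i * (-ln(max(T_i, floor)))`, with the band weights
#' taken to incorporate the path-length and solid-angle factors of the
#' commercial-analyzer convention.  A gap fraction of exactly zero would
#' give infinite LAI, so fractions are clamped at `floor` before the log;
#' when computed from a mask the natural floor is one sky pixel out of the
#' band's pixel count.
#'
#' @param gap_fractions Numeric vector of gap fractions in `[0, 1]`, one
#'   per band.
#' @param bands A [zenith_bands()].
#' @param floor Positive clamp applied below; scalar or one value per band.
#' @return Non-negative LAI (unitless).  Attribute `"floor"` records the
#'   clamp used.
#' @examples
#' estimate_lai(rep(exp(-1), 5))  # 2 * sum(weights) = 2.020
#' @export
estimate_lai <- function(gap_fractions, bands = zenith_bands(),
                         floor = 1e-6) {
  if (length(gap_fractions) != length(bands$centers)) {
    abort("One gap fraction per band is required.")
  }
  if (any(gap_fractions < 0 | gap_fractions > 1)) {
    abort("Gap fractions must lie in [0, 1].")
  }
  if (any(floor <= 0)) abort("`floor` must be positive.")
  lai <- 2 * sum(bands$weights * (-log(pmax(gap_fractions, floor))))
  attr(lai, "floor") <- floor
  lai
}

#' All canopy metrics of a mask as one tibble row
#'
#' Computes porosity, the per-band gap fractions and the LAI inversion in
#' one call.  The LAI floor is set per band to `1 / band pixel count`.
#'
#' @param mask A [sky_mask()].
#' @param bands A [zenith_bands()].
#' @return A one-row tibble: `source_id`, `threshold`, `porosity`,
#'   `t1..t5`, `lai`, `n_valid`.
#' @export
canopy_metrics <- function(mask, bands = zenith_bands()) {
  tf <- band_gap_fractions(mask, bands)
  counts <- band_pixel_counts(mask, bands)
  lai <- estimate_lai(tf, bands, floor = 1 / counts)
  out <- tibble(source_id = mask$source_id, threshold = mask$threshold,
                porosity = porosity(mask))
  out[names(tf)] <- as.list(tf)
  out$lai <- as.numeric(lai)
  out$n_valid <- sum(!is.na(mask$grid))
  out
}
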