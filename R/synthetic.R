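#' Generate a synthetic sky mask
#'
#' Two generators stand in for field photographs.  `"bernoulli"` makes each
#' valid pixel sky independently with the probability of its zenith band
#' (each pixel takes the probability of its nearest band centre) — an
#' estimator oracle, because the expected gap fractions are known exactly.
#' `"discs"` scatters opaque angular discs over an all-sky hemisphere
#' (centres uniform on the sphere cap, count Poisson in the cap solid
#' angle) — a clumped canopy closer to real foliage.
#'
#' @param geometry A [fisheye_geometry()]; the grid is sized to enclose the
#'   field-of-view circle.
#' @param mode `"bernoulli"` or `"discs"`.
#' @param band_probs Five sky probabilities, one per band (`"bernoulli"`).
#' @param bands A [zenith_bands()].
#' @param disc_density Expected disc count per steradian (`"discs"`).
#' @param disc_radius Disc angular radius in degrees (`"discs"`).
#' @param seed Mandatory integer seed; generation is bit-reproducible.
#' @param source_id Identifier stored in the mask.
#' @return A [sky_mask()].
#' @examples
#' geom <- fisheye_geometry(76, 76, 75)
#' m <- gen_mask(geom, band_probs = rep(0.5, 5), seed = 1)
#' porosity(m)
#' @export
gen_mask <- function(geometry, mode = c("bernoulli", "discs"),
                     band_probs = rep(0.5, 5), bands = zenith_bands(),
                     disc_density = 5, disc_radius = 10, seed,
                     source_id = NULL) {
  mode <- match.arg(mode)
  if (missing(seed)) abort("`seed` is mandatory for reproducible masks.")
  if (mode == "bernoulli" && any(band_probs < 0 | band_probs > 1)) {
    abort("`band_probs` must lie in [0, 1].")
  }
  if (mode == "bernoulli" && length(band_probs) != length(bands$centers)) {
    abort("One probability per band is required.")
  }
  if (disc_density < 0) abort("`disc_density` must be non-negative.")
  set.seed(seed)
  size <- c(ceiling(geometry$center_row + geometry$radius_px),
            ceiling(geometry$center_col + geometry$radius_px))
  dg <- direction_grid(size, geometry)
  grid <- matrix(NA, size[1], size[2])
  idx <- which(dg$valid)
  z <- dg$zenith[idx]
  if (mode == "bernoulli") {
    # constant probability within each band (nearest band centre), so band
    # gap fractions have exactly the planted expectation
    mids <- (head(bands$centers, -1) + tail(bands$centers, -1)) / 2
    p <- band_probs[findInterval(z, mids) + 1]
    grid[idx] <- runif(length(idx)) < p
    source_id <- source_id %||% sprintf("bernoulli-seed%d", seed)
  } else {
    cap_sr <- 2 * pi * (1 - cos(deg2rad(geometry$max_zenith)))
    n_discs <- rpois(1, disc_density * cap_sr)
    sky <- rep(TRUE, length(idx))
    if (n_discs > 0) {
      cz <- rad2deg(acos(runif(n_discs, cos(deg2rad(geometry$max_zenith)), 1)))
      ca <- runif(n_discs, 0, 360)
      pv <- direction_unit_vectors(z, dg$azimuth[idx])
      cv <- direction_unit_vectors(cz, ca)
      cosr <- cos(deg2rad(disc_radius))
      for (d in seq_len(n_discs)) {
        hit <- pv$e * cv$e[d] + pv$n * cv$n[d] + pv$u * cv$u[d] >= cosr
        sky[hit] <- FALSE
      }
    }
    grid[idx] <- sky
    source_id <- source_id %||% sprintf("discs-d%g-seed%d", disc_density, seed)
  }
  sky_mask(grid, geometry, source_id = source_id)
}

#' Generate a synthetic daily met series
#'
#' Emulates a CIMIS-style daily global-radiation export: each day's
#' measured value is the open-site clear-sky total scaled by a cloudiness
#' factor drawn from a Beta distribution, so every value stays at or below
#' the clear-sky envelope.
#'
#' @param start_date,end_date Window bounds (inclusive).
#' @param config A [radiation_config()].
#' @param shape1,shape2 Beta parameters of the cloudiness factor; `NULL`
#'   for a degenerate cloudless factor of 1.
#' @param seed Mandatory integer seed.
#' @return A tibble: `date`, `solar_rad_MJ_m2`, `clear_sky_MJ_m2`,
#'   `cloud_factor`.
#' @export
gen_met_series <- function(start_date, end_date, config,
                           shape1 = 8, shape2 = 2, seed) {
  if (missing(seed)) abort("`seed` is mandatory for reproducible series.")
  dates <- seq(as.Date(start_date), as.Date(end_date), by = "day")
  clear <- clear_sky_daily(dates, config)
  set.seed(seed)
  f <- if (is.null(shape1) || is.null(shape2)) rep(1, length(dates)) else
    rbeta(length(dates), shape1, shape2)
  tibble(date = dates, solar_rad_MJ_m2 = clear$total_MJ * f,
         clear_sky_MJ_m2 = clear$total_MJ, cloud_factor = f)
}

#' Generate piecewise-linear dose-response data with a known breakpoint
#'
#' Doses are uniform over `dose_range`; the response is a one-breakpoint
#' piecewise-linear function plus Gaussian noise.  The default breakpoint
#' of 544.2 MJ m^-2 anchors the generator at the dose where the percent
#' kaempferol response changes slope in ripening Cabernet Sauvignon (560.2
#' is the analogous anchor for total flavonols per berry).
#'
#' @param n Number of clusters (default 48, a two-trellis, 24-vine design).
#' @param psi_true Breakpoint dose, MJ m^-2.
#' @param slope_left,slope_right Segment slopes (response units per MJ m^-2).
#' @param intercept Response at dose 0.
#' @param noise_sd Gaussian noise SD in response units.
#' @param dose_range Dose window, MJ m^-2; must straddle `psi_true`.
#' @param seed Mandatory integer seed.
#' @return A tibble: `dose`, `response`, `mu` (noise-free mean).
#' @export
gen_response <- function(n = 48, psi_true = 544.2, slope_left = 0.01,
                         slope_right = 0.05, intercept = 2,
                         noise_sd = 0.5, dose_range = c(150, 950), seed) {
  if (missing(seed)) abort("`seed` is mandatory for reproducible data.")
  if (n < 10) abort("`n` must be at least 10.")
  if (psi_true <= dose_range[1] || psi_true >= dose_range[2]) {
    abort("`dose_range` must straddle `psi_true`.")
  }
  set.seed(seed)
  dose <- runif(n, dose_range[1], dose_range[2])
  mu <- intercept + slope_left * dose +
    (slope_right - slope_left) * pmax(dose - psi_true, 0)
  tibble(dose = dose, response = mu + rnorm(n, 0, noise_sd), mu = mu)
}

#' Generate a synthetic HPLC-DAD peak table
#'
#' Builds 365 nm peak records whose class percentages match a target
#' profile exactly (before jitter).  The quercetin class is split across
#' its three glycosides by fixed fractions.  Defaults follow the mean
#' profile of a sprawling-canopy Cabernet Sauvignon vineyard
#' (kaempferol 5.40, quercetin 51.5, myricetin 31.7 percent, remainder
#' split over the methylated classes).
#'
#' @param target_percentages Named numeric vector over the six aglycone
#'   classes, summing to 100.
#' @param total_area Total 365 nm peak area to distribute; must be
#'   positive.
#' @param quercetin_split Fractions of the quercetin class going to the
#'   galactoside, glucuronide and glucoside (sums to 1).
#' @param jitter_sd SD of optional lognormal area jitter (0 = off).
#' @param sample_id Identifier column value.
#' @param seed Seed, required only when `jitter_sd > 0`.
#' @return A tibble of peak records: `sample_id`, `compound`, `rt_min`,
#'   `area`.
#' @export
gen_peak_table <- function(target_percentages = c(
                             kaempferol = 5.40, quercetin = 51.5,
                             myricetin = 31.7, isorhamnetin = 3.8,
                             laricitrin = 3.8, syringetin = 3.8),
                           total_area = 1e5,
                           quercetin_split = c(0.2, 0.3, 0.5),
                           jitter_sd = 0, sample_id = "sample", seed = NULL) {
  if (total_area <= 0) abort("`total_area` must be positive.")
  if (abs(sum(target_percentages) - 100) > 1e-6) {
    abort("`target_percentages` must sum to 100.")
  }
  if (!all(flavonol_class_names %in% names(target_percentages))) {
    abort("`target_percentages` must name all six aglycone classes.")
  }
  if (abs(sum(quercetin_split) - 1) > 1e-9) {
    abort("`quercetin_split` must sum to 1.")
  }
  class_area <- total_area * target_percentages[flavonol_class_names] / 100
  compounds <- c("kaempferol-3-O-glucoside", "quercetin-3-O-galactoside",
                 "quercetin-3-O-glucuronide", "quercetin-3-O-glucoside",
                 "myricetin-3-O-glucoside", "isorhamnetin-3-O-glucoside",
                 "laricitrin-3-O-glucoside", "syringetin-3-O-glucoside")
  rt <- c(52, 33, 35, 38, 25, 55, 46, 58)   # plausible elution order, min
  area <- c(class_area[["kaempferol"]],
            class_area[["quercetin"]] * quercetin_split,
            class_area[["myricetin"]], class_area[["isorhamnetin"]],
            class_area[["laricitrin"]], class_area[["syringetin"]])
  if (jitter_sd > 0) {
    if (is.null(seed)) abort("`seed` is required when `jitter_sd` > 0.")
    set.seed(seed)
    area <- area * exp(rnorm(length(area), 0, jitter_sd))
  }
  tibble(sample_id = sample_id, compound = compounds, rt_min = rt,
         area = as.numeric(area))
}
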