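#' Radiation model configuration
#'
#' Site and model settings for the sun-path radiation simulation.
#'
#' @param latitude,longitude Site coordinates in degrees (longitude
#'   east-positive; western hemisphere sites are negative).
#' @param utc_offset Hours to add to UTC to obtain local standard time
#'   (e.g. -8 for California).  Timestamps given as character strings are
#'   interpreted in local standard time via this offset; no daylight-saving
#'   logic is applied.
#' @param timestep Simulation timestep in minutes (default 10).
#' @param solar_constant Extraterrestrial irradiance, W m^-2 (default 1367).
#' @param tau Clear-sky atmospheric transmittance per unit air mass
#'   (default 0.70).  Only the within-day shape matters once doses are
#'   corrected with measured daily radiation.
#' @param diffuse_fraction Diffuse radiation as a fraction of direct under
#'   clear sky (default 0.15); diffuse is modulated by canopy porosity but
#'   not by cloud cover.
#' @param beam_radius Angular radius in degrees of the disc sampled around
#'   the sun's image position (default 2); damps single-pixel noise.
#' @param correction_cap Upper cap on the daily met correction factor
#'   (default 1.2), a guard against met-unit errors.
#' @return An object of class `radiation_config`.
#' @export
radiation_config <- function(latitude, longitude, utc_offset,
                             timestep = 10, solar_constant = 1367,
                             tau = 0.70, diffuse_fraction = 0.15,
                             beam_radius = 2, correction_cap = 1.2) {
  if (abs(latitude) > 90) abort("`latitude` must be within [-90, 90].")
  if (timestep <= 0 || timestep > 60) abort("`timestep` must be in (0, 60] minutes.")
  if (tau <= 0 || tau >= 1) abort("`tau` must be in (0, 1).")
  if (diffuse_fraction < 0 || diffuse_fraction >= 1) {
    abort("`diffuse_fraction` must be in [0, 1).")
  }
  structure(
    list(latitude = latitude, longitude = longitude, utc_offset = utc_offset,
         timestep = timestep, solar_constant = solar_constant, tau = tau,
         diffuse_fraction = diffuse_fraction, beam_radius = beam_radius,
         correction_cap = correction_cap),
    class = "radiation_config"
  )
}

# parse times: POSIXct taken as absolute; character interpreted as local
# standard time shifted to UTC by the config offset
as_utc_time <- function(time, config) {
  if (inherits(time, "POSIXct")) {
    return(as.POSIXct(format(time, tz = "UTC"), tz = "UTC"))
  }
  as.POSIXct(time, tz = "UTC") - config$utc_offset * 3600
}

julian_day <- function(time_utc) {
  as.numeric(time_utc) / 86400 + 2440587.5
}

#' Solar position
#'
#' Computes the sun's elevation and compass azimuth from standard solar
#' geometry: geometric mean longitude and anomaly of the sun, equation of
#' centre, apparent ecliptic longitude, obliquity with nutation correction,
#' declination, equation of time, and hour angle.  Atmospheric refraction
#' is not applied.  Accuracy is a few hundredths of a degree over
#' 1950-2100.
#'
#' @param time A `POSIXct` vector (any timezone; the absolute instant is
#'   used) or character timestamps interpreted as local standard time via
#'   `config$utc_offset`.
#' @param config A [radiation_config()].
#' @return A tibble: `time` (UTC), `elevation`, `azimuth` (degrees;
#'   azimuth 0 = north, clockwise), `declination`, `hour_angle`.
#' @examples
#' cfg <- radiation_config(38.428, -122.409, utc_offset = -8)
#' sun_position("2017-07-24 12:00:00", cfg)  # local solar noon-ish
#' @export
sun_position <- function(time, config) {
  t_utc <- as_utc_time(time, config)
  yr <- as.integer(format(t_utc, "%Y"))
  if (any(yr < 1950 | yr > 2100)) {
    abort("Timestamps must lie within 1950-2100.")
  }
  jd <- julian_day(t_utc)
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + T * (36000.76983 + 0.0003032 * T)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  ecc <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  Mr <- deg2rad(M)
  eq_center <- sin(Mr) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * T) + sin(3 * Mr) * 0.000289
  omega <- deg2rad(125.04 - 1934.136 * T)
  lambda <- deg2rad(L0 + eq_center - 0.00569 - 0.00478 * sin(omega))
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) / 60) / 60
  eps <- deg2rad(eps0 + 0.00256 * cos(omega))
  decl <- asin(sin(eps) * sin(lambda))
  y <- tan(eps / 2)^2
  L0r <- deg2rad(L0)
  eqtime <- 4 * rad2deg(
    y * sin(2 * L0r) - 2 * ecc * sin(Mr) +
      4 * ecc * y * sin(Mr) * cos(2 * L0r) -
      0.5 * y^2 * sin(4 * L0r) - 1.25 * ecc^2 * sin(2 * Mr))
  frac_min <- (jd + 0.5 - floor(jd + 0.5)) * 1440   # minutes since UTC midnight
  tst <- (frac_min + eqtime + 4 * config$longitude) %% 1440
  ha <- deg2rad(tst / 4 - 180)
  lat <- deg2rad(config$latitude)
  sin_el <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  elevation <- rad2deg(asin(pmin(1, pmax(-1, sin_el))))
  azimuth <- rad2deg(atan2(
    -sin(ha) * cos(decl),
    cos(lat) * sin(decl) - sin(lat) * cos(decl) * cos(ha))) %% 360
  tibble(time = t_utc, elevation = elevation, azimuth = azimuth,
         declination = rad2deg(decl), hour_angle = rad2deg(ha))
}

#' Clear-sky direct irradiance on the horizontal
#'
#' Beer-law clear-sky model: `S0 * tau^AM * sin(elevation)` with the
#' Kasten-Young air-mass formula, zero at or below the horizon.  Absolute
#' calibration is carried by the daily met correction in
#' [accumulate_radiation()]; only the within-day shape matters here.
#'
#' @param elevation Solar elevation in degrees (vectorised).
#' @param config A [radiation_config()].
#' @return Irradiance in W m^-2.
#' @export
clear_sky_direct <- function(elevation, config) {
  am <- 1 / (sin(deg2rad(elevation)) +
               0.50572 * (elevation + 6.07995)^(-1.6364))
  out <- config$solar_constant * config$tau^am * sin(deg2rad(elevation))
  out[elevation <= 0] <- 0
  out
}

#' Beam transmission through the canopy toward the sun
#'
#' Fraction of sky pixels inside the angular disc of radius
#' `config$beam_radius` around the sun's image position.  Exactly zero when
#' the sun is below the horizon or its zenith angle exceeds the mask's
#' field of view (the unseen 75-90 degree ring is treated as blocked).
#'
#' @param mask A [sky_mask()].
#' @param elevation,azimuth Sun position in degrees (scalars).
#' @param config A [radiation_config()].
#' @return A fraction in `[0, 1]`.
#' @export
beam_transmission <- function(mask, elevation, azimuth, config) {
  stopifnot(inherits(mask, "sky_mask"))
  zen <- 90 - elevation
  if (elevation <= 0 || zen > mask$geometry$max_zenith) return(0)
  beam_transmission_impl(mask, zen, azimuth, config$beam_radius)
}

beam_transmission_impl <- function(mask, sun_zenith, sun_azimuth, beam_radius) {
  g <- mask$geometry
  radial <- zenith_to_radial(sun_zenith, g)
  bearing <- deg2rad(sun_azimuth - g$azimuth_offset)
  px <- list(row = g$center_row - radial * cos(bearing),
             col = g$center_col + radial * sin(bearing))
  # candidate window around the sun pixel; exact angular test inside
  halfw <- ceiling(zenith_to_radial(min(sun_zenith + beam_radius, g$max_zenith), g) -
                     zenith_to_radial(max(sun_zenith - beam_radius, 0), g)) + 2
  halfw <- max(halfw, ceiling(g$radius_px * beam_radius / g$max_zenith) + 2)
  rows <- max(1, floor(px$row - halfw)):min(nrow(mask$grid), ceiling(px$row + halfw))
  cols <- max(1, floor(px$col - halfw)):min(ncol(mask$grid), ceiling(px$col + halfw))
  z <- mask$directions$zenith[rows, cols, drop = FALSE]
  a <- mask$directions$azimuth[rows, cols, drop = FALSE]
  sky <- mask$grid[rows, cols, drop = FALSE]
  ok <- !is.na(z)
  if (!any(ok)) return(0)
  sv <- direction_unit_vectors(sun_zenith, sun_azimuth)
  pv <- direction_unit_vectors(z[ok], a[ok])
  cosd <- pv$e * sv$e + pv$n * sv$n + pv$u * sv$u
  inside <- cosd >= cos(deg2rad(beam_radius))
  if (!any(inside)) {
    # disc smaller than the pixel pitch: fall back to the nearest valid pixel
    return(as.numeric(sky[ok][which.max(cosd)]))
  }
  mean(sky[ok][inside])
}

#' Open-site clear-sky daily totals
#'
#' Daily global (direct plus diffuse) clear-sky dose at an unobstructed
#' site, by quadrature of [clear_sky_direct()] at the configured timestep.
#' Used as the denominator of the daily met correction and as the envelope
#' for synthetic met series.
#'
#' @param dates A `Date` vector.
#' @param config A [radiation_config()].
#' @return A tibble: `date`, `direct_MJ`, `diffuse_MJ`, `total_MJ`.
#' @export
clear_sky_daily <- function(dates, config) {
  purrr::map_dfr(as.list(as.Date(dates)), function(d) {
    st <- day_steps(d, config)
    direct <- sum(st$direct_wm2) * config$timestep * 60 / 1e6
    tibble(date = d, direct_MJ = direct,
           diffuse_MJ = config$diffuse_fraction * direct,
           total_MJ = (1 + config$diffuse_fraction) * direct)
  })
}

# solar positions and clear-sky direct at timestep midpoints of one day
# (local standard time 00:00-24:00)
day_steps <- function(date, config) {
  mins <- seq(config$timestep / 2, 1440 - config$timestep / 2,
              by = config$timestep)
  t_utc <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
    mins * 60 - config$utc_offset * 3600
  pos <- sun_position(t_utc, config)
  pos$direct_wm2 <- clear_sky_direct(pos$elevation, config)
  pos
}

#' Accumulate a per-cluster radiation dose over a date window
#'
#' Simulates the sun's trajectory at the configured timestep across every
#' day of `[start_date, end_date]`.  Per timestep, the direct component is
#' clear-sky direct irradiance times the mask's beam transmission toward
#' the sun, rescaled by the daily correction factor
#' `c_d = measured_global(d) / modeled open-sky clear-sky total(d)`
#' (capped at `config$correction_cap`).  The diffuse component is
#' `diffuse_fraction` times clear-sky direct, modulated by canopy porosity
#' but left on the clear-sky envelope (no cloud correction).  Energies are
#' integrated to MJ m^-2.
#'
#' @param mask A [sky_mask()].
#' @param config A [radiation_config()].
#' @param met A data frame with columns `date` and `solar_rad_MJ_m2`
#'   (measured daily global radiation) covering the whole window, e.g. from
#'   [gen_met_series()] or a CIMIS-style daily export.
#' @param start_date,end_date Window bounds (inclusive), `Date` or
#'   `"YYYY-MM-DD"`.
#' @return An object of class `radiation_summary`: totals `direct_MJ`,
#'   `diffuse_MJ`, `total_MJ`, window bounds, `n_timesteps`, and a per-day
#'   tibble `days`.
#' @export
accumulate_radiation <- function(mask, config, met, start_date, end_date) {
  stopifnot(inherits(mask, "sky_mask"), inherits(config, "radiation_config"))
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date < start_date) abort("`end_date` is before `start_date`.")
  dates <- seq(start_date, end_date, by = "day")
  met <- as_tibble(met)
  met$date <- as.Date(met$date)
  missing_days <- setdiff(as.character(dates), as.character(met$date))
  if (length(missing_days)) {
    abort(sprintf("Met series is missing %d day(s) in the window (first: %s).",
                  length(missing_days), missing_days[1]))
  }
  por <- porosity(mask)
  dt_s <- config$timestep * 60
  cap_hit <- FALSE
  days <- purrr::map_dfr(as.list(dates), function(d) {
    st <- day_steps(d, config)
    clear_direct_MJ <- sum(st$direct_wm2) * dt_s / 1e6
    clear_total_MJ <- clear_direct_MJ * (1 + config$diffuse_fraction)
    measured <- met$solar_rad_MJ_m2[match(d, met$date)]
    c_d <- if (clear_total_MJ > 0) measured / clear_total_MJ else 0
    if (c_d > config$correction_cap) {
      cap_hit <<- TRUE
      c_d <- config$correction_cap
    }
    up <- which(st$direct_wm2 > 0 &
                  (90 - st$elevation) <= mask$geometry$max_zenith)
    beam <- vapply(up, function(i) {
      beam_transmission_impl(mask, 90 - st$elevation[i], st$azimuth[i],
                             config$beam_radius)
    }, numeric(1))
    direct_MJ <- c_d * sum(st$direct_wm2[up] * beam) * dt_s / 1e6
    diffuse_MJ <- config$diffuse_fraction * clear_direct_MJ * por
    tibble(date = d, c_d = c_d, clear_direct_MJ = clear_direct_MJ,
           direct_MJ = direct_MJ, diffuse_MJ = diffuse_MJ,
           total_MJ = direct_MJ + diffuse_MJ)
  })
  if (cap_hit) {
    inform(sprintf("Daily met correction capped at %.2f on at least one day.",
                   config$correction_cap))
  }
  structure(
    list(direct_MJ = sum(days$direct_MJ), diffuse_MJ = sum(days$diffuse_MJ),
         total_MJ = sum(days$total_MJ), start_date = start_date,
         end_date = end_date,
         n_timesteps = length(dates) * (1440 / config$timestep),
         porosity = por, source_id = mask$source_id, days = days),
    class = "radiation_summary"
  )
}

#' @export
print.radiation_summary <- function(x, ...) {
  cat(sprintf(
    "<radiation_summary> '%s' %s to %s: direct %.1f + diffuse %.1f = %.1f MJ m-2\n",
    x$source_id, x$start_date, x$end_date,
    x$direct_MJ, x$diffuse_MJ, x$total_MJ))
  invisible(x)
}

#' @method tidy radiation_summary
#' @export
tidy.radiation_summary <- function(x, ...) x$days

#' @method glance radiation_summary
#' @export
glance.radiation_summary <- function(x, ...) {
  tibble(source_id = x$source_id, direct_MJ = x$direct_MJ,
         diffuse_MJ = x$diffuse_MJ, total_MJ = x$total_MJ,
         start_date = x$start_date, end_date = x$end_date,
         mean_daily = mean_daily_dose(x))
}

#' Mean daily radiation dose
#'
#' Accumulated dose divided by the elapsed days of the window (calendar
#' difference `end - start`).  A dose of 550 MJ m^-2 accumulated from
#' 24 July to 9 September (47 days) is 11.7 MJ m^-2 per day.
#'
#' @param total Accumulated dose in MJ m^-2, or a `radiation_summary`
#'   (its window is then used).
#' @param start_date,end_date Window bounds; `end_date` must be after
#'   `start_date`.
#' @return MJ m^-2 day^-1.
#' @export
mean_daily_dose <- function(total, start_date = NULL, end_date = NULL) {
  if (inherits(total, "radiation_summary")) {
    start_date <- start_date %||% total$start_date
    end_date <- end_date %||% total$end_date
    total <- total$total_MJ
  }
  ndays <- as.numeric(as.Date(end_date) - as.Date(start_date))
  if (ndays <= 0) abort("`end_date` must be after `start_date`.")
  total / ndays
}

#' Plot the daily radiation breakdown
#'
#' @param object A `radiation_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot radiation_summary
#' @export
autoplot.radiation_summary <- function(object, ...) {
  d <- tidyr::pivot_longer(object$days, c("direct_MJ", "diffuse_MJ"),
                           names_to = "component", values_to = "MJ")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$date, y = .data$MJ,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "dose (MJ m⁻² day⁻¹)",
                  title = object$source_id) +
    ggplot2::theme_minimal()
}
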