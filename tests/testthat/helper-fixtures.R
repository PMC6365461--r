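# shared fixtures: small geometries, uniform masks, a fast radiation config

test_geometry <- function(radius = 100, max_zenith = 75, offset = 0) {
  fisheye_geometry(center_row = radius + 1, center_col = radius + 1,
                   radius_px = radius, max_zenith = max_zenith,
                   azimuth_offset = offset)
}

uniform_mask <- function(sky = TRUE, radius = 100, max_zenith = 75,
                         offset = 0, id = if (sky) "allsky" else "allcanopy") {
  g <- test_geometry(radius, max_zenith, offset)
  n <- 2 * radius + 1
  sky_mask(matrix(sky, n, n), g, source_id = id)
}

oakville_config <- function(...) {
  radiation_config(latitude = 38.428, longitude = -122.409,
                   utc_offset = -8, ...)
}

# met series pinned to the clear-sky envelope, so every c_d = 1
clear_met <- function(config, start, end) {
  clear <- clear_sky_daily(seq(as.Date(start), as.Date(end), by = "day"),
                           config)
  tibble::tibble(date = clear$date, solar_rad_MJ_m2 = clear$total_MJ)
}

# Benchmark instants computed independently with the Michalsky (1988)
# Astronomical Almanac algorithm (no refraction); elevations/azimuths in
# degrees, timestamps UTC.
solar_benchmarks <- tibble::tribble(
  ~utc,                  ~lat,    ~lon,      ~elevation, ~azimuth,
  "2017-03-20 20:00:00",  38.428, -122.409,  51.534,     173.178,
  "2017-06-21 20:00:00",  38.428, -122.409,  74.806,     169.841,
  "2017-12-21 20:00:00",  38.428, -122.409,  28.107,     177.926,
  "2017-07-24 15:00:00",  38.428, -122.409,  20.489,      80.581,
  "2017-09-09 23:30:00",  38.428, -122.409,  33.142,     247.267,
  "2017-08-15 02:00:00",  38.428, -122.409,  11.396,     278.958,
  "2016-09-22 18:00:00",  38.660, -122.910,  41.950,     136.130,
  "2016-07-01 21:00:00",  35.580, -120.630,  72.908,     226.354,
  "2000-01-01 12:00:00",   0.000,    0.000,  66.953,     178.060,
  "2030-06-21 12:00:00",  51.500,    0.000,  61.932,     179.102,
  "2017-01-15 14:00:00", -33.900,   18.400,  47.566,     275.431,
  "2017-04-10 13:00:00",  38.428, -122.409,  -8.515,      72.451
)

# blue-channel RGB array on [0, 255]
blue_image <- function(blue_matrix) {
  arr <- array(0, dim = c(nrow(blue_matrix), ncol(blue_matrix), 3))
  arr[, , 3] <- blue_matrix / 255
  arr
}
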