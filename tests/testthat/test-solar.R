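test_that("solar position stays within 0.5 degrees of an independent ephemeris", {
  for (i in seq_len(nrow(solar_benchmarks))) {
    b <- solar_benchmarks[i, ]
    cfg <- radiation_config(b$lat, b$lon, utc_offset = 0)
    pos <- sun_position(as.POSIXct(b$utc, tz = "UTC"), cfg)
    expect_lt(abs(pos$elevation - b$elevation), 0.5)
    az_err <- abs(pos$azimuth - b$azimuth)
    expect_lt(min(az_err, 360 - az_err), 0.5)
  }
})

test_that("night and noon behave as solar geometry requires", {
  cfg <- oakville_config()
  # local midnight: sun far below the horizon
  expect_lt(sun_position("2017-08-01 00:00:00", cfg)$elevation, 0)
  # summer solar noon at a northern mid-latitude: azimuth about 180
  noon <- sun_position("2017-06-21 12:10:00", cfg)
  expect_lt(abs(noon$azimuth - 180), 2)
  expect_gt(noon$elevation, 70)
  expect_error(sun_position("1940-01-01 12:00:00", cfg), "1950-2100")
})

test_that("clear-sky direct follows the Beer-law closed form", {
  cfg <- oakville_config()
  expect_equal(clear_sky_direct(-5, cfg), 0)
  expect_equal(clear_sky_direct(0, cfg), 0)
  # zenith sun: air mass ~1, irradiance = 1367 * 0.70
  expect_equal(clear_sky_direct(90, cfg), 1367 * 0.70, tolerance = 1e-3)
  # strictly increasing in elevation
  irr <- clear_sky_direct(seq(1, 90, 0.5), cfg)
  expect_true(all(diff(irr) > 0))
})

test_that("beam transmission samples the solar disc and blocks the unseen ring", {
  cfg <- oakville_config()
  expect_equal(beam_transmission(uniform_mask(TRUE), 60, 180, cfg), 1)
  expect_equal(beam_transmission(uniform_mask(FALSE), 60, 180, cfg), 0)
  # zenith angle beyond max_zenith (the omitted 75-90 ring): blocked
  expect_equal(beam_transmission(uniform_mask(TRUE), 10, 180, cfg), 0)
  expect_equal(beam_transmission(uniform_mask(TRUE), -3, 180, cfg), 0)
  # half-plane mask: sky for azimuth < 180, canopy otherwise; a disc on the
  # boundary sees about half sky (a wider disc keeps pixel quantization of
  # the boundary column well below the tolerance)
  cfg5 <- oakville_config(beam_radius = 5)
  g <- test_geometry(radius = 200)
  m0 <- uniform_mask(TRUE, radius = 200)
  grid <- m0$directions$azimuth < 180
  m <- sky_mask(grid, g)
  bt <- beam_transmission(m, 50, 180, cfg5)
  expect_lt(abs(bt - 0.5), 0.05)
  bt0 <- beam_transmission(m, 50, 0, cfg5)
  expect_lt(abs(bt0 - 0.5), 0.05)
})

test_that("all-sky accumulation matches direct quadrature with c_d = 1", {
  cfg <- oakville_config(timestep = 10)
  mask <- uniform_mask(TRUE, radius = 60, max_zenith = 90)
  met <- clear_met(cfg, "2017-08-01", "2017-08-05")
  s <- accumulate_radiation(mask, cfg, met, "2017-08-01", "2017-08-05")
  # independent 1-minute quadrature of clear_sky_direct * (1 + f)
  oracle <- 0
  for (d in as.list(met$date)) {
    tt <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC") +
      seq(0.5, 1439.5, 1) * 60 + 8 * 3600
    el <- sun_position(tt, cfg)$elevation
    oracle <- oracle + sum(clear_sky_direct(el, cfg)) * 60 / 1e6 * 1.15
  }
  expect_lt(abs(s$total_MJ - oracle) / oracle, 0.01)
  expect_equal(s$total_MJ, s$direct_MJ + s$diffuse_MJ)
})

test_that("occlusion is monotone: removing sky pixels cannot raise the dose", {
  cfg <- oakville_config(timestep = 30)
  g <- test_geometry(radius = 60)
  met <- clear_met(cfg, "2017-08-01", "2017-08-03")
  m_big <- gen_mask(g, band_probs = rep(0.8, 5), seed = 50)
  grid_small <- m_big$grid & (matrix(runif(121 * 121), 121, 121) < 0.6)
  m_small <- sky_mask(grid_small, g)
  s_big <- accumulate_radiation(m_big, cfg, met, "2017-08-01", "2017-08-03")
  s_small <- accumulate_radiation(m_small, cfg, met, "2017-08-01", "2017-08-03")
  expect_lte(s_small$total_MJ, s_big$total_MJ)
  # all-canopy mask: exactly zero
  s0 <- accumulate_radiation(uniform_mask(FALSE, radius = 60), cfg, met,
                             "2017-08-01", "2017-08-03")
  expect_equal(s0$total_MJ, 0)
})

test_that("doubling the timestep changes the clear-day total by under 1%", {
  mask <- uniform_mask(TRUE, radius = 60, max_zenith = 90)
  t10 <- clear_sky_daily(as.Date("2017-08-01"), oakville_config(timestep = 10))
  t20 <- clear_sky_daily(as.Date("2017-08-01"), oakville_config(timestep = 20))
  expect_lt(abs(t20$total_MJ - t10$total_MJ) / t10$total_MJ, 0.01)
})

test_that("accumulated dose is invariant under joint mask/offset rotation", {
  cfg <- oakville_config(timestep = 30)
  met <- clear_met(cfg, "2017-08-01", "2017-08-02")
  g0 <- test_geometry(radius = 60, offset = 0)
  m0 <- gen_mask(g0, band_probs = c(0.9, 0.7, 0.5, 0.3, 0.2), seed = 61)
  # rotate the grid 90 deg clockwise and compensate with azimuth_offset 90:
  # pixels image the same compass directions, so the dose must not change
  rot_grid <- t(m0$grid)[ncol(m0$grid):1, ]
  g90 <- test_geometry(radius = 60, offset = 90)
  m90 <- sky_mask(rot_grid, g90)
  s0 <- accumulate_radiation(m0, cfg, met, "2017-08-01", "2017-08-02")
  s90 <- accumulate_radiation(m90, cfg, met, "2017-08-01", "2017-08-02")
  expect_equal(s90$total_MJ, s0$total_MJ, tolerance = 0.01)
})

test_that("the daily met correction rescales direct beam only", {
  cfg <- oakville_config(timestep = 10, diffuse_fraction = 0.15)
  mask <- uniform_mask(TRUE, radius = 60, max_zenith = 90)
  met <- clear_met(cfg, "2017-08-01", "2017-08-02")
  met$solar_rad_MJ_m2 <- met$solar_rad_MJ_m2 * 0.6    # cloudy days
  s <- accumulate_radiation(mask, cfg, met, "2017-08-01", "2017-08-02")
  # each day's direct equals measured * direct share of the clear model
  expect_equal(s$days$direct_MJ, met$solar_rad_MJ_m2 / 1.15,
               tolerance = 1e-6)
  # diffuse stays on the clear-sky envelope (porosity 1 here)
  expect_equal(s$days$diffuse_MJ, 0.15 * s$days$clear_direct_MJ,
               tolerance = 1e-9)
  # with diffuse_fraction 0 the total is the met-corrected direct integral
  cfg0 <- oakville_config(timestep = 10, diffuse_fraction = 0)
  met0 <- clear_met(cfg0, "2017-08-01", "2017-08-02")
  met0$solar_rad_MJ_m2 <- met0$solar_rad_MJ_m2 * 0.6
  s0 <- accumulate_radiation(mask, cfg0, met0, "2017-08-01", "2017-08-02")
  expect_equal(s0$total_MJ, sum(met0$solar_rad_MJ_m2), tolerance = 1e-6)
})

test_that("met gaps and reversed windows are errors; cap is applied", {
  cfg <- oakville_config(timestep = 30)
  mask <- uniform_mask(TRUE, radius = 60)
  met <- clear_met(cfg, "2017-08-01", "2017-08-02")
  expect_error(accumulate_radiation(mask, cfg, met, "2017-08-01", "2017-08-05"),
               "missing")
  expect_error(accumulate_radiation(mask, cfg, met, "2017-08-02", "2017-08-01"),
               "before")
  met_bad <- dplyr::mutate(met, solar_rad_MJ_m2 = solar_rad_MJ_m2 * 5)
  expect_message(
    s <- accumulate_radiation(mask, cfg, met_bad, "2017-08-01", "2017-08-02"),
    "capped")
  expect_true(all(s$days$c_d <= 1.2))
})

test_that("mean daily dose divides by elapsed calendar days", {
  # the ripening window 24 July - 9 September spans 47 days
  expect_equal(mean_daily_dose(550, "2017-07-24", "2017-09-09"), 11.7,
               tolerance = 0.005)
  expect_equal(mean_daily_dose(0, "2017-07-24", "2017-09-09"), 0)
  expect_equal(mean_daily_dose(100, "2017-08-01", "2017-08-11"), 10)
  expect_error(mean_daily_dose(100, "2017-08-01", "2017-08-01"), "after")
})
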