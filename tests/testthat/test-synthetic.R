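test_that("generators are bit-reproducible given a seed", {
  g <- test_geometry(radius = 40)
  m1 <- gen_mask(g, band_probs = rep(0.5, 5), seed = 60)
  m2 <- gen_mask(g, band_probs = rep(0.5, 5), seed = 60)
  expect_identical(m1$grid, m2$grid)
  cfg <- oakville_config(timestep = 60)
  s1 <- gen_met_series("2017-08-01", "2017-08-10", cfg, seed = 61)
  s2 <- gen_met_series("2017-08-01", "2017-08-10", cfg, seed = 61)
  expect_identical(s1, s2)
  r1 <- gen_response(seed = 62); r2 <- gen_response(seed = 62)
  expect_identical(r1, r2)
  expect_error(gen_mask(g, band_probs = rep(0.5, 5)), "seed")
})

test_that("bernoulli masks honour degenerate probabilities", {
  g <- test_geometry(radius = 40)
  expect_equal(porosity(gen_mask(g, band_probs = rep(1, 5), seed = 63)), 1)
  expect_equal(porosity(gen_mask(g, band_probs = rep(0, 5), seed = 63)), 0)
  expect_error(gen_mask(g, band_probs = c(0.5, 1.2, 0, 0, 0), seed = 1),
               "\\[0, 1\\]")
})

test_that("disc-mode porosity decreases with disc density", {
  g <- test_geometry(radius = 60)
  expect_equal(porosity(gen_mask(g, "discs", disc_density = 0, seed = 64)), 1)
  dens <- c(1, 3, 6, 12, 24)
  # average over seeds: Boolean-model coverage grows with density
  por <- vapply(dens, function(dd) {
    mean(vapply(1:5, function(s) {
      porosity(gen_mask(g, "discs", disc_density = dd, disc_radius = 10,
                        seed = 640 + s * 7 + round(dd)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(por) < 0))
})

test_that("met series stay within the clear-sky envelope", {
  cfg <- oakville_config(timestep = 60)
  s <- gen_met_series("2017-07-24", "2017-08-24", cfg, seed = 65)
  expect_true(all(s$solar_rad_MJ_m2 <= s$clear_sky_MJ_m2 + 1e-9))
  expect_true(all(s$cloud_factor > 0 & s$cloud_factor <= 1))
  # cloudless degenerate factor
  s0 <- gen_met_series("2017-08-01", "2017-08-05", cfg, shape1 = NULL,
                       shape2 = NULL, seed = 66)
  expect_equal(s0$solar_rad_MJ_m2, s0$clear_sky_MJ_m2)
})

test_that("Beta(8, 2) cloudiness factors average 0.8", {
  set.seed(67)
  f <- rbeta(1000, 8, 2)
  se <- sqrt(8 * 2 / ((8 + 2)^2 * 11)) / sqrt(1000)
  expect_lt(abs(mean(f) - 0.8), 3 * se)
})

test_that("noise-free response data recovers the planted breakpoint exactly", {
  d <- gen_response(n = 48, psi_true = 544.2, noise_sd = 0, seed = 68)
  f <- segmented_fit(d, "dose", "response")
  expect_lt(abs(f$psi - 544.2), 1e-4)
  # equal slopes: degenerate
  d2 <- gen_response(n = 48, slope_left = 0.02, slope_right = 0.02,
                     noise_sd = 0, seed = 69)
  f2 <- segmented_fit(d2, "dose", "response")
  expect_false(f2$converged)
  expect_error(gen_response(psi_true = 100, dose_range = c(150, 950),
                            seed = 1), "straddle")
})

test_that("replicated noisy fits centre on the kaempferol-anchor breakpoint", {
  # noise at roughly 10% response CV, a 48-cluster design
  psis <- vapply(1:400, function(s) {
    d <- gen_response(n = 48, psi_true = 544.2, noise_sd = 0.5,
                      seed = 2000 + s)
    segmented_fit(d, "dose", "response")$psi
  }, numeric(1))
  se <- sd(psis) / sqrt(length(psis))
  expect_lt(abs(mean(psis) - 544.2), 2 * se)
})

test_that("peak tables round-trip through quantification and profiling", {
  pk <- gen_peak_table()
  pr <- aglycone_profile(quantify_peaks(pk, 10))
  expect_equal(pr$pct_kaempferol, 5.40, tolerance = 1e-4)
  expect_equal(pr$pct_quercetin, 51.5, tolerance = 1e-4)
  expect_equal(pr$pct_myricetin, 31.7, tolerance = 1e-4)
  # arbitrary target percentages reproduce to 0.01%
  tgt <- c(kaempferol = 12, quercetin = 40, myricetin = 28,
           isorhamnetin = 8, laricitrin = 7, syringetin = 5)
  pr2 <- aglycone_profile(quantify_peaks(gen_peak_table(tgt), 10))
  got <- as.numeric(pr2[paste0("pct_", names(tgt))])
  expect_true(all(abs(got - tgt) < 0.01))
  expect_error(gen_peak_table(total_area = 0), "positive")
  expect_error(gen_peak_table(c(kaempferol = 50, quercetin = 40,
                                myricetin = 28, isorhamnetin = 8,
                                laricitrin = 7, syringetin = 5)), "sum to 100")
})
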