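eight_peaks <- function(areas) {
  tibble::tibble(
    compound = c("myricetin-3-O-glucoside", "quercetin-3-O-galactoside",
                 "quercetin-3-O-glucuronide", "quercetin-3-O-glucoside",
                 "kaempferol-3-O-glucoside", "isorhamnetin-3-O-glucoside",
                 "laricitrin-3-O-glucoside", "syringetin-3-O-glucoside"),
    area = areas)
}

test_that("quantification is linear in area with one shared response factor", {
  pk <- eight_peaks(c(0, 100, 0, 0, 0, 0, 0, 0))
  q <- quantify_peaks(pk, response_factor = 10)
  expect_equal(q$conc_mg_l[q$compound == "quercetin-3-O-galactoside"], 10)
  expect_equal(q$conc_mg_l[q$compound == "myricetin-3-O-glucoside"], 0)
  # two peaks of one compound are summed: (30 + 20) / 10 = 5
  dup <- tibble::tibble(compound = rep("quercetin-3-O-glucoside", 2),
                        area = c(30, 20))
  expect_equal(quantify_peaks(dup, 10)$conc_mg_l, 5)
  expect_error(quantify_peaks(dup, 0), "positive")
  expect_error(quantify_peaks(tibble::tibble(compound = "rutin", area = 1), 10),
               "Unknown compound")
  expect_error(quantify_peaks(tibble::tibble(
    compound = "quercetin-3-O-glucoside", area = -1), 10), "non-negative")
})

test_that("aglycone profile pools the quercetin glycosides and sums to 100", {
  pk <- eight_peaks(c(30, 10, 20, 20, 5, 5, 5, 5) * 10)
  pr <- aglycone_profile(quantify_peaks(pk, 10))
  expect_equal(pr$pct_quercetin, 50)
  expect_equal(pr$pct_myricetin, 30)
  expect_equal(pr$pct_kaempferol, 5)
  expect_equal(pr$pct_isorhamnetin, 5)
  expect_equal(pr$pct_laricitrin, 5)
  expect_equal(pr$pct_syringetin, 5)
  expect_equal(methylated_share(pr), 15)
  # single nonzero class takes 100%
  solo <- aglycone_profile(quantify_peaks(
    eight_peaks(c(100, 0, 0, 0, 0, 0, 0, 0)), 10))
  expect_equal(solo$pct_myricetin, 100)
  expect_equal(methylated_share(solo), 0)
  expect_error(aglycone_profile(quantify_peaks(eight_peaks(rep(0, 8)), 10)),
               "undefined")
})

test_that("per-berry content follows the extraction unit factors", {
  # 10 mg/L * 1 mL * (25 mg berry skin / 50 mg aliquot) = 0.005 mg per berry
  conc <- tibble::tibble(class = "kaempferol", conc_mg_l = 10)
  pr <- aglycone_profile(conc, meta = list(extract_volume = 1,
                                           aliquot_mass = 50,
                                           skin_dry_mass_per_berry = 25))
  expect_equal(pr$total_mg_per_berry, 0.005)
  # linear in extract volume and skin mass
  pr2 <- aglycone_profile(conc, meta = list(extract_volume = 2,
                                            aliquot_mass = 50,
                                            skin_dry_mass_per_berry = 25))
  expect_equal(pr2$total_mg_per_berry, 0.010)
  pr3 <- aglycone_profile(conc, meta = list(extract_volume = 1,
                                            aliquot_mass = 50,
                                            skin_dry_mass_per_berry = 50))
  expect_equal(pr3$total_mg_per_berry, 0.010)
  # per-berry output without the required meta is refused, never defaulted
  expect_error(aglycone_profile(conc, meta = list(extract_volume = 1)),
               "skin_dry_mass_per_berry")
  # without meta the percentages are exact and the total is NA
  pr4 <- aglycone_profile(conc)
  expect_true(is.na(pr4$total_mg_per_berry))
  expect_equal(pr4$pct_kaempferol, 100)
})

test_that("profiles are scale-free and order-invariant", {
  set.seed(30)
  areas <- runif(8, 10, 1000)
  pk <- eight_peaks(areas)
  pr1 <- aglycone_profile(quantify_peaks(pk, 10))
  pr2 <- aglycone_profile(quantify_peaks(eight_peaks(areas * 7.3), 10))
  expect_equal(pr1[paste0("pct_", c("kaempferol", "quercetin", "myricetin",
                                    "isorhamnetin", "laricitrin", "syringetin"))],
               pr2[paste0("pct_", c("kaempferol", "quercetin", "myricetin",
                                    "isorhamnetin", "laricitrin", "syringetin"))])
  shuffled <- pk[sample(8), ]
  pr3 <- aglycone_profile(quantify_peaks(shuffled, 10))
  expect_equal(pr1$pct_quercetin, pr3$pct_quercetin)
  # percentages always sum to 100
  pcts <- as.numeric(pr1[grep("^pct_", names(pr1))])
  expect_equal(sum(pcts), 100, tolerance = 1e-9)
})

test_that("the compound map accepts the laricitin spelling variant", {
  pk <- tibble::tibble(
    compound = c("laricitin-3-O-glucoside", "laricitrin-3-O-glucoside"),
    area = c(10, 10))
  q <- quantify_peaks(pk, 10)
  expect_true(all(q$class == "laricitrin"))
  pr <- aglycone_profile(q)
  expect_equal(pr$pct_laricitrin, 100)
})
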