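# canopylux

Solar-radiation exposure of grape clusters from hemispherical canopy
photographs, and its relationship to berry flavonol composition.

## The problem

How much light did *this* cluster actually receive over ripening?  Berry
flavonols — the six aglycone classes kaempferol, quercetin, myricetin,
isorhamnetin, laricitrin and syringetin, quantified by HPLC-DAD at
365 nm — are strongly induced by solar radiation, and the *profile*
(each class as a percentage of total flavonols, especially % kaempferol)
is a candidate integrating dosimeter of cluster exposure.  Testing that
idea needs a per-cluster radiation dose, which canopylux derives from a
single upward-looking fisheye photograph:

1. **Sky segmentation** — one global threshold on the blue channel turns
   the photo into a binary sky/canopy mask (`binarize_blue()`,
   `otsu_threshold()`).
2. **Canopy metrics** — porosity (sky fraction), gap fractions T̄ᵢ of
   five 13°-wide zenith bands at 7/23/38/53/68°, and the five-ring
   inversion LAI = 2 Σᵢ Wᵢ(−ln T̄ᵢ) with the commercial-analyzer weights
   W = (0.034, 0.104, 0.160, 0.218, 0.494) (`canopy_metrics()`).
3. **Radiation dose** — the sun's trajectory is simulated over a date
   window; per timestep the direct beam is clear-sky irradiance × the
   sky fraction of a small angular disc around the sun's image position,
   rescaled by a daily correction cₔ = measured / modelled clear-sky
   global from a met station; diffuse is 15% of clear-sky direct scaled
   by porosity, uncorrected for cloud.  Doses accumulate to MJ m⁻²
   (`accumulate_radiation()`).
4. **Flavonol profiling** — 365 nm peak areas → concentrations in
   quercetin-3-O-glucoside equivalents via a single response factor →
   class percentages and (with extraction metadata) mg per berry
   (`quantify_peaks()`, `aglycone_profile()`).
5. **Statistics** — one-breakpoint segmented regression
   (`segmented_fit()`), Pearson correlation with the spatially corrected
   (Clifford–Richardson) modified t-test (`pearson_modified()`), and
   one-way ANOVA with Fisher's LSD compact letters (`anova_lsd()`).

Synthetic generators (`gen_mask()`, `gen_met_series()`,
`gen_response()`, `gen_peak_table()`) produce every input with known
truth, so the whole chain is testable without field data.

## Worked example

A synthetic cluster photograph, a season of met data, and the full chain
to a breakpoint fit:

```r
library(canopylux)

geom <- fisheye_geometry(center_row = 101, center_col = 101, radius_px = 100)
mask <- gen_mask(geom, mode = "discs", disc_density = 6, disc_radius = 10,
                 seed = 11)
canopy_metrics(mask)
#> # A tibble: 1 × 10
#>   source_id       threshold porosity    t1    t2    t3    t4    t5   lai n_valid
#> 1 discs-d6-seed11        NA    0.652 0.801 0.633 0.753 0.594 0.623 0.895   31417

cfg <- radiation_config(latitude = 38.428, longitude = -122.409,
                        utc_offset = -8)
met <- gen_met_series("2017-07-24", "2017-09-09", cfg, seed = 12)
dose <- accumulate_radiation(mask, cfg, met, "2017-07-24", "2017-09-09")
dose
#> <radiation_summary> 'discs-d6-seed11' 2017-07-24 to 2017-09-09:
#>   direct 644.6 + diffuse 101.3 = 745.9 MJ m-2
mean_daily_dose(dose)
#> [1] 15.86993
```

This cluster saw 65% sky, a canopy-density index (LAI) of 0.9, and
accumulated 745.9 MJ m⁻² of global radiation over the 47-day ripening
window — 15.9 MJ m⁻² per day.  Its flavonol profile and the
dose–response breakpoint across a 48-cluster design:

```r
peaks <- gen_peak_table(sample_id = "cluster-01")
aglycone_profile(quantify_peaks(peaks, response_factor = 10))
#> # A tibble: 1 × 8
#>   sample_id  pct_kaempferol pct_quercetin pct_myricetin pct_isorhamnetin ...
#> 1 cluster-01            5.4          51.5          31.7              3.8

d <- gen_response(n = 48, psi_true = 544.2, seed = 13)
fit <- segmented_fit(d, x = "dose", y = "response")
fit
#> <segmented_fit> psi = 533.7 (SE 6.32), slopes 0.01008 -> 0.04896, iterative, n = 48
autoplot(fit)
```

The planted breakpoint of 544.2 MJ m⁻² is recovered at 533.7 ± 6.3 from
one noisy 48-point replicate; the percentages are the generator's
targets returned exactly by the profiling chain.  `run_exposure()` and
`run_profile_analysis()` orchestrate the same steps for whole image sets
and joined covariate tables.

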