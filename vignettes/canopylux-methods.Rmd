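---
title: "From hemispherical photographs to flavonol dose-response: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From hemispherical photographs to flavonol dose-response: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopylux)
```

canopylux estimates how much solar radiation a grape cluster accumulated
over ripening from a single upward-looking fisheye photograph, and relates
that exposure to the berry's flavonol content and aglycone profile.  This
vignette explains each model in the chain, the assumptions behind it, the
tunable parameters, and the choices made where the design was genuinely
open.

## Sky segmentation

Sky and canopy separate well on the blue channel of an RGB photograph:
sky pixels are bright in blue, foliage is dark.  `binarize_blue()` applies
one global threshold (default 128 on the 8-bit scale) to the blue channel,
and the same threshold is meant to be applied identically to every image
of a campaign, so that differences between masks reflect canopies rather
than per-image threshold adaptation.  `otsu_threshold()` offers a
data-driven alternative: the classic maximisation of between-class
variance, by exhaustive search over the 256 candidate 8-bit thresholds,
computed once on the pooled blue histogram of the whole image set.

Two things are deliberately *not* done.  There is no gamma correction —
thresholds are defined on stored pixel values, and a campaign should fix
its exposure settings instead.  And there is no tilt support: the optical
axis is assumed vertical, with the zenith at the image centre.

## Projection geometry

The lens is modelled as an equidistant (equi-angular) fisheye: radial
pixel distance from the optical centre is proportional to zenith angle,
$r = R\,\theta/\theta_{\max}$.  This is the standard assumption in
hemispherical canopy photography and is accurate enough for band-level
gap statistics; an equisolid option (`projection = "equisolid"`) exists
for lenses known to follow $r \propto \sin(\theta/2)$.  A 150° lens sees
zenith angles 0–75°; the unseen 75–90° ring is treated as blocked when
the sun passes through it, which in hedged vineyard rows is close to the
truth because neighbouring canopies occupy exactly those directions.

Azimuths are compass bearings (0 = north, clockwise) everywhere in the
package; `azimuth_offset` records where the image "up" direction pointed.
Pixels outside the field-of-view circle are flagged invalid and never
enter a numerator or a denominator.

## Porosity, gap fractions and the LAI inversion

Canopy porosity is simply the sky fraction of valid pixels.  Gap
fractions $\bar T_i$ are sky fractions within five 13°-wide zenith bands
centred at 7°, 23°, 38°, 53° and 68° — the ring layout of commercial
plant canopy analyzers — with band membership decided by half-open
intervals $[c_i - 6.5°, c_i + 6.5°)$ so boundary pixels belong to exactly
one band.  The leaf area index inversion is

$$\mathrm{LAI} = 2 \sum_{i=1}^{5} W_i \left(-\ln \bar T_i\right),$$

with weights $W = (0.034, 0.104, 0.160, 0.218, 0.494)$ taken to
incorporate the path-length and solid-angle factors of the analyzer
convention.  The printed weights sum to 1.010; they are used as printed
by default, with `normalize = TRUE` available.  Because vines are not
random media, this "LAI" includes non-leafy vegetation and clumping bias;
it is used as a canopy-density index, not a literal leaf area.

A gap fraction of exactly zero would make the inversion infinite, so
fractions are clamped below at a floor before the log.  When metrics are
computed from a mask, the floor is one sky pixel out of the band's pixel
count — the smallest observable non-zero fraction — and the floor used is
recorded on the result.

## Sun path and the radiation dose

`sun_position()` implements the standard high-accuracy solar geometry
(geometric mean longitude and anomaly, equation of centre, apparent
ecliptic longitude, corrected obliquity, equation of time and hour
angle), good to a few hundredths of a degree over 1950–2100; the test
suite pins it against twelve benchmark instants computed independently
with the Michalsky Astronomical Almanac algorithm.  No atmospheric
refraction is applied — at the elevations that matter for canopy
interception it is far below the angular width of a pixel.

Clear-sky direct irradiance on the horizontal uses a Beer-law
transmittance model, $S_0 \tau^{AM} \sin h$, with the Kasten–Young air
mass.  The transmittance $\tau$ (default 0.70) deliberately carries no
absolute calibration burden: measured daily radiation rescales every
day's beam, so only the within-day *shape* of the clear-sky curve
matters.  Doubling the 10-minute default timestep changes a clear-day
total by under 1%.

The accumulated dose over a window combines, per timestep,

* **direct**: clear-sky direct × beam transmission × daily correction
  $c_d$, where beam transmission is the sky fraction of an angular disc
  (default radius 2°) around the sun's image position — a disc rather
  than one pixel, to damp pixel noise — and exactly zero below the
  horizon or in the unseen 75–90° ring;
* **diffuse**: 15% of clear-sky direct (the `diffuse_fraction` default),
  scaled by canopy porosity as an all-sky view factor, and *not* rescaled
  by $c_d$ — the working assumption is that diffuse rides the clear-sky
  envelope, modulated by the canopy but not by cloud cover.

The daily correction $c_d$ is the measured daily global radiation divided
by the modelled open-site clear-sky total for that day.  It is capped at
1.2 as a guard against unit errors in met inputs (a message reports when
the cap bites).  Timestamps are local standard time via an explicit UTC
offset; there is no daylight-saving logic, by design — met loggers
usually run on standard time.

Mean daily dose divides the accumulated total by the calendar-day
difference of the window: a 550 MJ m⁻² total over 24 July – 9 September
(47 days) is 11.7 MJ m⁻² day⁻¹.

## Flavonol quantification and profile

HPLC-DAD peak areas at 365 nm are converted to concentrations with a
single response factor against quercetin-3-O-glucoside, the common
single-standard practice for grape flavonols; per-compound molar response
factors are deliberately not supported, so results stay in
quercetin-3-O-glucoside equivalents.  The eight glycosides map to six
aglycone classes (the quercetin class pools galactoside, glucuronide and
glucoside; "laricitin" is accepted as an alternative spelling of
laricitrin), and the map ships as an editable CSV.

Profile percentages are scale-free — they need no extraction metadata.
Per-berry contents do: extract volume and skin dry mass per berry are
required inputs with **no defaults**, because any silently assumed volume
would fabricate per-berry numbers.  When the metadata is absent the
per-berry column is `NA` and the percentages are still exact.

## Segmented regression

`segmented_fit()` estimates one breakpoint by iterative linearization:
the working model is augmented with $U = (x-\psi)_+$ and
$V = -\mathbb{1}(x>\psi)$ and the breakpoint is updated by
$\psi \leftarrow \psi + \hat\gamma/\hat\beta$ until the step falls below
$10^{-6}\,\mathrm{range}(x)$ (at most 50 iterations).  If the iteration
diverges or leaves the interior of the data, an exhaustive
residual-sum-of-squares search over interior $x$ values takes over, with
ties broken toward the smaller breakpoint; the `method` field records
which route produced the estimate.  The breakpoint standard error comes
from the delta method on $\gamma/\beta$.  An exactly linear response is
reported with `converged = FALSE` rather than a fabricated interior
breakpoint; no formal test for the *existence* of a breakpoint is
provided — users who need one should look at Davies-type tests elsewhere.

## Spatially corrected correlation

For samples on a spatial grid, positive autocorrelation makes the
classical correlation t-test anticonservative.  `pearson_modified()`
implements the Clifford–Richardson correction: the null variance of $r$
is estimated from products of the two variables' spatial
autocorrelations over distance classes, which yields an effective sample
size $M \le n$ (up to estimation noise) and a t-test on $M - 2$ degrees
of freedom.  The number of distance classes follows Sturges' rule on the
pair count with a minimum of five — the reference implementations do not
document a universal setting, and the estimate is insensitive to the
class count at the sample sizes involved.  Without coordinates the
function reduces *exactly* to the classical test, and the result records
which test was used.  Duplicating every site exactly halves the effective
sample size, which the tests verify against the constructed expectation.

## ANOVA with LSD letters

`anova_lsd()` is a one-way ANOVA followed by Fisher's least significant
difference at level $\alpha$ (default 0.05) and a compact letter display
assigned by the insert-and-absorb procedure, so two groups share a letter
exactly when their difference is below their pairwise LSD.  Unbalanced
groups use pairwise $\sqrt{MSE(1/n_i + 1/n_j)}$; the scalar `lsd` field
reports the harmonic-mean-size LSD for display.  No multiplicity
correction is applied on top of the LSD — results are reported per panel,
matching how such letter tables are conventionally read.

## What the synthetic generators emulate — and what they do not

Every input the pipeline consumes can be generated:

* `gen_mask()` in *bernoulli* mode draws each pixel independently with
  its band's probability.  Real canopies are nothing like this — the mode
  exists because its expected gap fractions are known exactly, making it
  an estimator oracle.  *Discs* mode scatters opaque angular discs
  (Poisson count over the sky cap, centres uniform on the sphere) and
  supplies the clumping that makes doses and LAI behave like real
  canopies.  Neither mode renders leaves, stems, or the strong azimuthal
  anisotropy of a trellised row.
* `gen_met_series()` multiplies open-site clear-sky daily totals by
  Beta-distributed cloudiness factors (default Beta(8, 2), mean 0.8 — a
  dry Mediterranean ripening season), so synthetic series never exceed
  the clear-sky envelope.  It does not emulate multi-day weather
  persistence.
* `gen_response()` plants a piecewise-linear dose–response with a known
  breakpoint and Gaussian noise.  The defaults anchor the breakpoint at
  544.2 MJ m⁻² (560.2 for total flavonols) with doses uniform over
  150–950 MJ m⁻², slopes 0.01 and 0.05 below/above, noise SD 0.5 —
  roughly a 10% response CV at a 48-cluster design.
* `gen_peak_table()` builds peak tables whose class percentages hit a
  target exactly (quercetin split 0.2/0.3/0.5 over galactoside,
  glucuronide, glucoside — arbitrary and irrelevant to class-level
  outputs), with optional lognormal jitter.

Passing tests on these generators therefore demonstrates that the
*estimators and plumbing* are correct under known truth; they cannot
validate the radiometric realism of the clear-sky model or the biology of
the dose–response on real vineyards.

All generators require an explicit seed and are bit-reproducible.

## Problem sizes and numerical choices in the checks

The test-suite and the acceptance script use deliberately modest problem
sizes chosen to exercise every contract: masks of 100–200 px radius
(≥ 10⁵ valid pixels where binomial tolerances demand it), the full
24 July – 9 September window at 10–30-minute timesteps, 200-replicate
breakpoint simulations at the 48-cluster design, and 500-replicate null
calibrations of the corrected t-test at n = 100.  Stochastic checks fix
their seeds and state binomial or Monte-Carlo tolerances (3σ bands, 2
standard errors) rather than ad-hoc epsilons.

## Known limitations

* One image ↔ one berry sample per `sample_id`; the linkage is a field
  protocol, not something the software can verify.
* The clear-sky model is a one-parameter Beer law; sites with strongly
  varying aerosol or humidity regimes should check the within-day shape
  against a pyranometer before trusting sub-daily partitioning.
* Reflected and ground-albedo radiation, spectral (UV-B) transfer and
  cluster temperature are out of scope.
* The equidistant projection is assumed, not calibrated; strongly
  non-equidistant lenses need the equisolid hook or external remapping.
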