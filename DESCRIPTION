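Package: canopylux
Title: Canopy Light Interception and Berry Flavonol Profiling from
    Hemispherical Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the solar-radiation exposure of grape clusters from
    hemispherical (fisheye) canopy photographs and relates that exposure to
    berry flavonol content and aglycone profile.  Segments sky from canopy
    on the blue channel, computes canopy porosity, zenith-band gap fractions
    and a five-ring leaf area index inversion, simulates the sun's path to
    accumulate a direct plus diffuse radiation dose corrected with measured
    daily meteorological radiation, converts HPLC-DAD peak tables at 365 nm
    into flavonol profiles, and provides the statistical tools used in this
    kind of study: one-breakpoint segmented regression, Pearson correlation
    with a spatial-autocorrelation-corrected (modified) t-test, and one-way
    ANOVA with Fisher's LSD compact letter displays.  Includes synthetic
    generators for every input so the full pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jpeg,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
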