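#' Flavonol compound to aglycone-class map
#'
#' The eight grape-skin flavonol glycosides quantified at 365 nm, mapped to
#' their six aglycone classes.  "laricitin" is accepted as an alternative
#' spelling of laricitrin.  The map ships as a plain CSV in
#' `inst/extdata/flavonol_compounds.csv` so it can be versioned and edited.
#'
#' @return A tibble with columns `compound` and `class`.
#' @export
flavonol_compounds <- function() {
  path <- system.file("extdata", "flavonol_compounds.csv",
                      package = "canopylux")
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

flavonol_class_names <- c("kaempferol", "quercetin", "myricetin",
                          "isorhamnetin", "laricitrin", "syringetin")

#' Quantify flavonol peaks against the quercetin-3-O-glucoside standard
#'
#' Converts 365 nm peak areas to concentrations in
#' quercetin-3-O-glucoside equivalents (QGE) using a single shared response
#' factor — the single-standard convention of calibrating every flavonol against one
#' quantitative standard.  Multiple peaks of the same compound are summed.
#'
#' @param peaks A data frame with columns `compound` and `area` (and
#'   optionally `sample_id`, `rt_min`).
#' @param response_factor Area units per mg L^-1 of
#'   quercetin-3-O-glucoside; must be positive.
#' @return A tibble with columns (`sample_id`,) `compound`, `class`,
#'   `conc_mg_l`.
#' @examples
#' peaks <- tibble::tibble(
#'   compound = c("quercetin-3-O-glucoside", "kaempferol-3-O-glucoside"),
#'   area = c(100, 20))
#' quantify_peaks(peaks, response_factor = 10)
#' @export
quantify_peaks <- function(peaks, response_factor) {
  if (!is.numeric(response_factor) || response_factor <= 0) {
    abort("`response_factor` must be a positive number.")
  }
  peaks <- as_tibble(peaks)
  if (any(peaks$area < 0)) abort("Peak areas must be non-negative.")
  map <- flavonol_compounds()
  unknown <- setdiff(unique(peaks$compound), map$compound)
  if (length(unknown)) {
    abort(sprintf("Unknown compound label(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  peaks$class <- map$class[match(peaks$compound, map$compound)]
  keys <- intersect(c("sample_id", "compound", "class"), names(peaks))
  peaks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(conc_mg_l = sum(.data$area) / response_factor,
                     .groups = "drop")
}

#' Aglycone profile and per-berry content
#'
#' Sums compound concentrations into the six aglycone classes (the
#' quercetin class pools the galactoside, glucuronide and glucoside) and
#' expresses each class as a percentage of the total.  When extraction
#' metadata is supplied, per-berry contents are computed as
#' `concentration (mg/L) x extract volume (L) x skin dry mass per berry /
#' aliquot mass`; without metadata the percentages are still exact and the
#' per-berry columns are `NA` — per-berry numbers are never fabricated from
#' default volumes.
#'
#' @param concentrations Output of [quantify_peaks()] (columns `class`,
#'   `conc_mg_l`, optional `sample_id`), or any data frame shaped like it.
#' @param meta Optional named list or one-row data frame with
#'   `extract_volume` (mL), `aliquot_mass` (mg, default 50) and
#'   `skin_dry_mass_per_berry` (mg).
#' @param sample_id Identifier used when `concentrations` carries none.
#' @return A one-row-per-sample tibble: `sample_id`, `pct_kaempferol`,
#'   `pct_quercetin`, `pct_myricetin`, `pct_isorhamnetin`,
#'   `pct_laricitrin`, `pct_syringetin`, `total_mg_per_berry`.
#' @export
aglycone_profile <- function(concentrations, meta = NULL,
                             sample_id = "sample") {
  conc <- as_tibble(concentrations)
  if (!"sample_id" %in% names(conc)) conc$sample_id <- sample_id
  if (!"class" %in% names(conc)) {
    map <- flavonol_compounds()
    conc$class <- map$class[match(conc$compound, map$compound)]
  }
  if (!all(conc$class %in% flavonol_class_names)) {
    abort("Unrecognised aglycone class in `concentrations`.")
  }
  scale <- NA_real_
  if (!is.null(meta)) {
    meta <- as.list(meta)
    req <- c("extract_volume", "skin_dry_mass_per_berry")
    missing_f <- req[!vapply(req, function(f) !is.null(meta[[f]]), logical(1))]
    if (length(missing_f)) {
      abort(sprintf("Per-berry output needs meta field(s): %s.",
                    paste(missing_f, collapse = ", ")))
    }
    aliquot <- meta$aliquot_mass %||% 50
    # mg/L * mL/1000 = mg in extract; scaled by berry skin share of aliquot
    scale <- (meta$extract_volume / 1000) *
      (meta$skin_dry_mass_per_berry / aliquot)
  }
  per_class <- conc |>
    dplyr::group_by(.data$sample_id, .data$class) |>
    dplyr::summarise(conc_mg_l = sum(.data$conc_mg_l), .groups = "drop") |>
    tidyr::complete(sample_id = unique(conc$sample_id),
                    class = flavonol_class_names,
                    fill = list(conc_mg_l = 0))
  totals <- per_class |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$conc_mg_l), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort("All concentrations are zero: the profile is undefined.")
  }
  per_class |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(pct = 100 * .data$conc_mg_l / .data$total) |>
    dplyr::select("sample_id", "class", "pct") |>
    tidyr::pivot_wider(names_from = "class", values_from = "pct",
                       names_prefix = "pct_") |>
    dplyr::select("sample_id", dplyr::all_of(paste0("pct_", flavonol_class_names))) |>
    dplyr::left_join(
      dplyr::mutate(totals, total_mg_per_berry = .data$total * scale),
      by = "sample_id") |>
    dplyr::select(-"total")
}

#' Share of methylated flavonols
#'
#' Sum of the isorhamnetin, laricitrin and syringetin percentages — the
#' methylated classes, which stay near-constant (around 18 percent) across
#' exposure levels while kaempferol and quercetin trade off against
#' myricetin.
#'
#' @param profile A profile tibble from [aglycone_profile()].
#' @return Numeric vector of percentages, one per row of `profile`.
#' @export
methylated_share <- function(profile) {
  profile$pct_isorhamnetin + profile$pct_laricitrin + profile$pct_syringetin
}
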