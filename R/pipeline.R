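#' Exposure pipeline: masks to canopy metrics and radiation dose
#'
#' Runs the image-to-dose chain for a set of sky masks: canopy porosity,
#' band gap fractions, the LAI inversion, and the met-corrected accumulated
#' radiation dose over the window.  A failure on one mask is caught,
#' recorded in the `error` column and the run continues; results are
#' deterministic given the inputs.
#'
#' @param masks A list of [sky_mask()] objects, or a directory of mask
#'   PNGs written by [write_mask_png()] (then `geometry` must be supplied).
#' @param config A [radiation_config()].
#' @param met Daily met table (see [accumulate_radiation()]).
#' @param start_date,end_date Radiation window (inclusive).
#' @param bands A [zenith_bands()].
#' @param geometry A [fisheye_geometry()] used when `masks` is a
#'   directory, or a data frame of per-image geometry (columns
#'   `source_id`, `center_row`, `center_col`, `radius_px`, `max_zenith`,
#'   `azimuth_offset`).
#' @return A tibble, one row per mask: `source_id`, `threshold`,
#'   `porosity`, `t1..t5`, `lai`, `n_valid`, `direct_MJ`, `diffuse_MJ`,
#'   `total_MJ`, `error`.
#' @export
run_exposure <- function(masks, config, met, start_date, end_date,
                         bands = zenith_bands(), geometry = NULL) {
  if (is.character(masks)) {
    masks <- load_mask_dir(masks, geometry)
  }
  if (!length(masks)) abort("Empty mask set.")
  purrr::map_dfr(masks, function(m) {
    tryCatch({
      met_row <- canopy_metrics(m, bands)
      summ <- accumulate_radiation(m, config, met, start_date, end_date)
      dplyr::bind_cols(met_row,
                       tibble(direct_MJ = summ$direct_MJ,
                              diffuse_MJ = summ$diffuse_MJ,
                              total_MJ = summ$total_MJ,
                              error = NA_character_))
    }, error = function(e) {
      warn(sprintf("Mask '%s' failed: %s", m$source_id, conditionMessage(e)))
      tibble(source_id = m$source_id, error = conditionMessage(e))
    })
  })
}

load_mask_dir <- function(dir, geometry) {
  paths <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  if (!length(paths)) abort(sprintf("No PNG masks found in '%s'.", dir))
  lapply(paths, function(p) {
    id <- sub("\\.png$", "", basename(p))
    g <- if (is.data.frame(geometry)) {
      row <- geometry[geometry$source_id == id, ]
      if (!nrow(row)) abort(sprintf("No geometry row for '%s'.", id))
      fisheye_geometry(row$center_row, row$center_col, row$radius_px,
                       row$max_zenith, row$azimuth_offset)
    } else geometry
    read_mask_png(p, g, source_id = id)
  })
}

#' Join exposure results with sample tables
#'
#' Inner join on `sample_id` (exposure rows join via `source_id`), with a
#' message counting dropped rows; silent imputation is never performed.
#'
#' @param exposure Output of [run_exposure()].
#' @param ... Further data frames keyed by `sample_id` (flavonol profiles,
#'   covariates).
#' @return The joined tibble.
#' @export
join_exposure_profiles <- function(exposure, ...) {
  out <- dplyr::rename(as_tibble(exposure), sample_id = "source_id")
  for (tbl in list(...)) {
    before <- nrow(out)
    out <- dplyr::inner_join(out, as_tibble(tbl), by = "sample_id")
    if (nrow(out) < before) {
      inform(sprintf("Join dropped %d unmatched row(s).", before - nrow(out)))
    }
  }
  out
}

#' Profile analysis: correlations, breakpoints, group comparisons
#'
#' Runs the statistical stage over a joined per-sample table: for every
#' requested variable pair a Pearson correlation (spatially corrected via
#' the modified t-test whenever coordinate columns are present, classical
#' otherwise), optionally a segmented fit for pairs flagged as
#' dose-response, and a one-way ANOVA with LSD letters when a grouping
#' column is named.  Analyses use pairwise-complete observations and the
#' used sample size is reported per pair.
#'
#' @param data Joined per-sample tibble (see [join_exposure_profiles()]).
#' @param pairs A data frame with columns `x`, `y` and optional logical
#'   `segmented`, naming columns of `data`.
#' @param coords Optional character vector of two coordinate column names;
#'   when present the corrected test is used.
#' @param group Optional name of a grouping column; every `y` of `pairs`
#'   is then also compared across groups with [anova_lsd()].
#' @param alpha Significance level for the LSD letters.
#' @return A list of class `profile_analysis`: `correlations` (tibble),
#'   `segments` (named list of [segmented_fit()] objects),
#'   `anova` (named list of [anova_lsd()] objects), `settings`.
#' @export
run_profile_analysis <- function(data, pairs, coords = NULL, group = NULL,
                                 alpha = 0.05) {
  data <- as_tibble(data)
  pairs <- as_tibble(pairs)
  if (!all(c("x", "y") %in% names(pairs))) {
    abort("`pairs` needs columns `x` and `y`.")
  }
  if (!"segmented" %in% names(pairs)) pairs$segmented <- FALSE
  missing_cols <- setdiff(unique(c(pairs$x, pairs$y, coords, group)),
                          names(data))
  if (length(missing_cols)) {
    abort(sprintf("Column(s) not in `data`: %s.",
                  paste(missing_cols, collapse = ", ")))
  }

  segments <- list()
  correlations <- purrr::pmap_dfr(pairs[c("x", "y", "segmented")],
                                  function(x, y, segmented) {
    d <- data[complete.cases(data[[x]], data[[y]]), ]
    if (nrow(d) < 4) {
      abort(sprintf("Pair %s ~ %s has %d complete rows; >= 4 required.",
                    y, x, nrow(d)))
    }
    if (sd(d[[x]]) == 0 || sd(d[[y]]) == 0) {
      return(tibble(x = x, y = y, n = nrow(d), r = NA_real_,
                    effective_n = NA_real_, p_value = NA_real_,
                    corrected = NA, note = "constant variable"))
    }
    ct <- pearson_modified(d, x, y, coords = coords)
    if (isTRUE(segmented)) {
      segments[[paste(y, "vs", x)]] <<- segmented_fit(d, x = x, y = y)
    }
    tibble(x = x, y = y, n = ct$n, r = ct$r, effective_n = ct$effective_n,
           p_value = ct$p_value, corrected = ct$corrected,
           note = NA_character_)
  })

  anova <- list()
  if (!is.null(group)) {
    for (y in unique(pairs$y)) {
      anova[[y]] <- anova_lsd(data, values = y, groups = group, alpha = alpha)
    }
  }
  structure(
    list(correlations = correlations, segments = segments, anova = anova,
         settings = list(coords = coords, group = group, alpha = alpha,
                         n_rows = nrow(data))),
    class = "profile_analysis"
  )
}

#' @export
print.profile_analysis <- function(x, ...) {
  cat(sprintf("<profile_analysis> %d pair(s), %d segmented fit(s), %d ANOVA(s)%s\n",
              nrow(x$correlations), length(x$segments), length(x$anova),
              if (is.null(x$settings$coords)) " (classical t-test)"
              else " (spatially corrected)"))
  print(x$correlations)
  invisible(x)
}

#' Write a profile analysis to CSV + JSON
#'
#' Emits `correlations.csv`, one `segment_*.json` fit record per segmented
#' pair, `anova_*.csv` letter tables, and a plain-text `report.txt` naming
#' every setting used.  Floats are written with fixed 15-digit formatting
#' so re-running an identical configuration reproduces byte-identical
#' files.
#'
#' @param analysis A `profile_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_profile_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) formatC(col, digits = 15, format = "g") else col)
    df
  }
  utils::write.csv(fmt(analysis$correlations),
                   file.path(dir, "correlations.csv"), row.names = FALSE)
  for (nm in names(analysis$segments)) {
    jsonlite::write_json(
      as.list(glance(analysis$segments[[nm]])),
      file.path(dir, paste0("segment_", gsub("[^a-zA-Z0-9]+", "_", nm), ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  for (nm in names(analysis$anova)) {
    utils::write.csv(fmt(analysis$anova[[nm]]$groups),
                     file.path(dir, paste0("anova_", nm, ".csv")),
                     row.names = FALSE)
  }
  s <- analysis$settings
  writeLines(c(
    sprintf("canopylux %s profile analysis",
            as.character(utils::packageVersion("canopylux"))),
    sprintf("rows analysed: %d", s$n_rows),
    sprintf("coordinates: %s",
            if (is.null(s$coords)) "none (classical t-test)"
            else paste(s$coords, collapse = ", ")),
    sprintf("grouping: %s", s$group %||% "none"),
    sprintf("alpha: %g", s$alpha)
  ), file.path(dir, "report.txt"))
  invisible(dir)
}
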