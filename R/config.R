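#' Analysis configuration
#'
#' Bundles the tunable choices shared across the analysis chain: the assay
#' limit of detection, the exposure dichotomization quantile, the high-BPA
#' cut used in the epigenetic analyses, the matching ratio, bootstrap sizes,
#' the dose-derivation constants and the seed.
#'
#' @param lod_value assay limit of detection, ug/L.
#' @param exposure_quantile quantile for the high/low exposure cut (default
#'   0.75: top quartile vs the rest).
#' @param high_bpa_cutoff_epigenetics ug/L cut for the categorical exposure
#'   contrast used in the methylation and mediation models (default 4).
#' @param contrast_mode `"gt4_vs_rest"` or `"gt4_vs_lt1"`; see
#'   [categorize_for_epigenetics()].
#' @param match_m controls matched per case (default 8).
#' @param seed root integer seed.
#' @param bootstrap_reps bootstrap replicates for interval estimation.
#' @param safety_factors unitless divisors applied when deriving a tolerable
#'   daily intake (default `c(10)`: human-sensitivity variability).
#' @param urine_output_l_per_day assumed daily urine output, L (default 1.6).
#' @param fractional_excretion fraction of intake excreted in urine, in
#'   (0, 1] (default 1).
#' @param bodyweight_kg reference maternal bodyweight, kg (default 80.1).
#' @param lod_policy how below-LOD values enter continuous log2 analyses:
#'   `"sqrt2"` imputes LOD/sqrt(2) (default), `"as_reported"` leaves them.
#' @param complete_case drop records with missing model covariates (default
#'   `TRUE`); made explicit because adjusted-model missingness handling is a
#'   reporting choice, not a statistical inevitability.
#'
#' @return an object of class `aroma_config` (a named list).
#' @export
aroma_config <- function(lod_value = 0.57,
                         exposure_quantile = 0.75,
                         high_bpa_cutoff_epigenetics = 4,
                         contrast_mode = c("gt4_vs_rest", "gt4_vs_lt1"),
                         match_m = 8L,
                         seed = 20260101L,
                         bootstrap_reps = 2000L,
                         safety_factors = c(10),
                         urine_output_l_per_day = 1.6,
                         fractional_excretion = 1.0,
                         bodyweight_kg = 80.1,
                         lod_policy = c("sqrt2", "as_reported"),
                         complete_case = TRUE) {
  contrast_mode <- match.arg(contrast_mode)
  lod_policy <- match.arg(lod_policy)
  stopifnot(
    lod_value > 0,
    exposure_quantile > 0, exposure_quantile < 1,
    high_bpa_cutoff_epigenetics > 0,
    match_m >= 1,
    bootstrap_reps >= 1,
    all(safety_factors > 0),
    urine_output_l_per_day > 0,
    fractional_excretion > 0, fractional_excretion <= 1,
    bodyweight_kg > 0
  )
  structure(list(
    lod_value = lod_value,
    exposure_quantile = exposure_quantile,
    high_bpa_cutoff_epigenetics = high_bpa_cutoff_epigenetics,
    contrast_mode = contrast_mode,
    match_m = as.integer(match_m),
    seed = as.integer(seed),
    bootstrap_reps = as.integer(bootstrap_reps),
    safety_factors = as.numeric(safety_factors),
    urine_output_l_per_day = urine_output_l_per_day,
    fractional_excretion = fractional_excretion,
    bodyweight_kg = bodyweight_kg,
    lod_policy = lod_policy,
    complete_case = isTRUE(complete_case)
  ), class = "aroma_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `aroma_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(aroma_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(aroma_config, vals)
}

#' @export
print.aroma_config <- function(x, ...) {
  cat("<aroma_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  cat(sprintf("  %-28s %s\n", "(hash)", config_hash(x)))
  invisible(x)
}
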