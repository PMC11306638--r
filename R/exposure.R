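#' Specific-gravity correction of urinary concentrations
#'
#' Rescales a urinary biomarker concentration for urine dilution using the
#' Levine-Fahy form: `conc * (sg_ref - 1) / (sg_obs - 1)`, with the reference
#' density conventionally the cohort median. Missing concentrations propagate
#' as missing.
#'
#' @param conc concentration, ug/L (vectorized; may contain `NA`).
#' @param sg_obs observed specific gravity (> 1).
#' @param sg_ref reference specific gravity (> 1), e.g. the cohort median.
#' @return corrected concentration, ug/L.
#' @export
sg_correct <- function(conc, sg_obs, sg_ref) {
  ok <- !is.na(sg_obs)
  if (any(sg_obs[ok] <= 1)) {
    stop("sg_correct: observed specific gravity <= 1 is physically invalid")
  }
  if (any(!is.na(sg_ref) & sg_ref <= 1)) {
    stop("sg_correct: reference specific gravity must exceed 1")
  }
  conc * (sg_ref - 1) / (sg_obs - 1)
}

#' Dichotomize exposure at an empirical quantile
#'
#' Flags concentrations strictly above the empirical quantile (type-7) of
#' the non-missing values; at a 0.75 quantile this is the top-quartile vs
#' rest contrast. Below-LOD values enter as reported: with heavy left
#' censoring the upper-quartile cut is unaffected by their exact values.
#'
#' @param concs concentrations, ug/L; `NA` allowed.
#' @param quantile cut quantile in (0, 1), default 0.75.
#' @return list with `high` (logical vector, `NA` where `concs` is missing)
#'   and `threshold` (the empirical quantile, ug/L).
#' @export
dichotomize_exposure <- function(concs, quantile = 0.75) {
  obs <- concs[!is.na(concs)]
  if (length(obs) == 0) stop("dichotomize_exposure: all exposures missing")
  if (length(obs) < 4) stop("dichotomize_exposure: need >= 4 non-missing values")
  thr <- stats::quantile(obs, probs = quantile, type = 7, names = FALSE)
  list(high = concs > thr, threshold = thr)
}

#' Categorize exposure for the epigenetic contrast
#'
#' `gt4_vs_rest`: above the cutoff (strictly) is exposed, everything else is
#' referent. `gt4_vs_lt1`: above the cutoff is exposed, below 1 ug/L is
#' referent, in between is excluded.
#'
#' @param conc concentrations, ug/L (non-missing).
#' @param mode `"gt4_vs_rest"` or `"gt4_vs_lt1"`.
#' @param cutoff exposed cutoff, ug/L (default 4).
#' @param referent_below referent cutoff for `gt4_vs_lt1` (default 1).
#' @return character vector in `{"exposed", "referent", "excluded"}`.
#' @export
categorize_for_epigenetics <- function(conc,
                                       mode = c("gt4_vs_rest", "gt4_vs_lt1"),
                                       cutoff = 4, referent_below = 1) {
  mode <- match.arg(mode)
  if (anyNA(conc)) stop("categorize_for_epigenetics: missing concentrations")
  if (mode == "gt4_vs_rest") {
    ifelse(conc > cutoff, "exposed", "referent")
  } else {
    ifelse(conc > cutoff, "exposed",
           ifelse(conc < referent_below, "referent", "excluded"))
  }
}

#' Impute below-LOD exposures for continuous analyses
#'
#' Left-censored values are replaced by `LOD/sqrt(2)` under the default
#' policy, or left as reported. Applied only where the censoring flag is set.
#'
#' @param conc concentrations, ug/L.
#' @param below_lod logical censoring flags.
#' @param lod limit of detection, ug/L.
#' @param policy `"sqrt2"` or `"as_reported"`.
#' @return concentrations with censored values handled per policy.
#' @export
impute_below_lod <- function(conc, below_lod, lod, policy = c("sqrt2", "as_reported")) {
  policy <- match.arg(policy)
  if (policy == "as_reported") return(conc)
  out <- conc
  idx <- which(!is.na(below_lod) & below_lod)
  out[idx] <- lod / sqrt(2)
  out
}

#' Convert a urinary concentration to an estimated daily intake
#'
#' Steady-state mass balance: intake (ng/kg/day) =
#' `conc * urine_output * 1000 / (fractional_excretion * bodyweight)`.
#' Alongside the exact value a floored integer presentation value is
#' returned, matching the convention of quoting intakes to whole ng/kg.
#'
#' @param conc urinary concentration, ug/L.
#' @param urine_output daily urine output, L/day.
#' @param fractional_excretion fraction of intake excreted in urine, (0, 1].
#' @param bodyweight bodyweight, kg.
#' @return list with `intake` (ng/kg/day, exact) and `presented` (floored).
#' @export
urinary_to_intake <- function(conc, urine_output = 1.6,
                              fractional_excretion = 1.0, bodyweight = 80.1) {
  stopifnot(urine_output > 0, fractional_excretion > 0,
            fractional_excretion <= 1)
  if (bodyweight <= 0) stop("urinary_to_intake: bodyweight must be positive")
  if (any(!is.na(conc) & conc < 0)) stop("urinary_to_intake: negative concentration")
  intake <- conc * urine_output * 1000 / (fractional_excretion * bodyweight)
  list(intake = intake, presented = floor(intake))
}

#' Apply safety factors to derive a tolerable daily intake
#'
#' Divides an intake by the product of the supplied unitless factors (e.g.
#' 10 for interspecies variability, 10 for human-sensitivity variability).
#' An empty factor list leaves the intake unchanged.
#'
#' @param intake ng/kg/day, >= 0.
#' @param factors numeric vector of positive divisors (may be empty).
#' @return ng/kg/day.
#' @export
apply_safety_factors <- function(intake, factors = numeric(0)) {
  stopifnot(all(intake >= 0, na.rm = TRUE))
  if (length(factors) && any(factors <= 0)) {
    stop("apply_safety_factors: factors must be positive")
  }
  intake / prod(factors)
}
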