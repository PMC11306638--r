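## Cohort tables: one row per child. Column conventions
##   subject_id            opaque id (character)
##   sex                   "male" / "female"
##   ancestry_caucasian4   all four grandparents Caucasian (logical)
##   urine_time_pm         maternal urine collected after 2 pm (logical)
##   bpa_raw / bpa_sg      urinary BPA, raw and specific-gravity corrected (ug/L)
##   bpa_below_lod         left-censoring flag
##   specific_gravity      urine density (unitless, > 1)
##   geno_<rsID>           genotype strings, two alleles ("CT" etc.)
##   asp_tscore            CBCL autism-spectrum-problems T-score (integer >= 28)
##   asd_dx9               verified DSM-5 ASD diagnosis by the year-9 review
##   dx_screen_date        ISO date of the year-9 health screen
##   dx_screen_age         age at screen, decimal years
##   cg<id>                methylation beta values in [0, 1]
##   cell_<type>           cord-blood cell proportions, each in [0, 1], sum <= 1
## Missing values are empty cells in CSV; no sentinel numbers.

genotype_cols <- function(cohort) grep("^geno_", names(cohort), value = TRUE)
cpg_cols <- function(cohort) grep("^cg", names(cohort), value = TRUE)
cell_cols <- function(cohort) grep("^cell_", names(cohort), value = TRUE)

#' Validate a cohort table against the subject-record invariants
#'
#' Checks: beta values in \[0, 1\]; `bpa_raw >= 0` where present; sex one of
#' male/female; specific gravity > 1 where present; ASP T-scores >= 28; cell
#' proportions in \[0, 1\] with row sums <= 1 (+ small tolerance); unique
#' subject ids. Errors name the first offending row and column.
#'
#' @param cohort a cohort data frame.
#' @return the cohort, invisibly, when valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  req <- c("subject_id", "sex")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("cohort lacks required columns: ", paste(miss, collapse = ", "))
  if (nrow(cohort) == 0) return(invisible(cohort))

  fail <- function(col, rows, why) {
    stop(sprintf("cohort validation failed: column '%s', row %d: %s",
                 col, rows[1], why), call. = FALSE)
  }
  if (anyDuplicated(cohort$subject_id)) {
    fail("subject_id", which(duplicated(cohort$subject_id)), "duplicated id")
  }
  bad <- which(!is.na(cohort$sex) & !cohort$sex %in% c("male", "female"))
  if (length(bad)) fail("sex", bad, "must be 'male' or 'female'")

  for (col in cpg_cols(cohort)) {
    v <- cohort[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) fail(col, bad, "beta value outside [0, 1]")
  }
  if ("bpa_raw" %in% names(cohort)) {
    bad <- which(!is.na(cohort$bpa_raw) & cohort$bpa_raw < 0)
    if (length(bad)) fail("bpa_raw", bad, "negative concentration")
  }
  if ("specific_gravity" %in% names(cohort)) {
    bad <- which(!is.na(cohort$specific_gravity) & cohort$specific_gravity <= 1)
    if (length(bad)) fail("specific_gravity", bad, "must exceed 1")
  }
  if ("asp_tscore" %in% names(cohort)) {
    bad <- which(!is.na(cohort$asp_tscore) & cohort$asp_tscore < 28)
    if (length(bad)) fail("asp_tscore", bad, "T-score below scale minimum 28")
  }
  cc <- cell_cols(cohort)
  if (length(cc)) {
    for (col in cc) {
      v <- cohort[[col]]
      bad <- which(!is.na(v) & (v < 0 | v > 1))
      if (length(bad)) fail(col, bad, "cell proportion outside [0, 1]")
    }
    sums <- rowSums(as.matrix(cohort[cc]), na.rm = TRUE)
    bad <- which(sums > 1 + 1e-8)
    if (length(bad)) fail(cc[1], bad, "cell proportions sum above 1")
  }
  invisible(cohort)
}

#' Read a cohort table from CSV/TSV
#'
#' Missing values must be empty cells. Dates are ISO-8601. Every row is
#' validated against the subject-record invariants; nothing is imputed.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file.
#' @param config an [aroma_config()]; currently only carried along for
#'   interface symmetry and future schema options.
#' @return a validated cohort data frame.
#' @export
read_cohort <- function(path, config = aroma_config()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (nrow(df) == 0) {
    warning("cohort file has a header but no records: ", path)
  } else {
    if ("dx_screen_date" %in% names(df)) {
      df$dx_screen_date <- as.Date(df$dx_screen_date)
    }
    for (col in intersect(c("ancestry_caucasian4", "urine_time_pm",
                            "bpa_below_lod", "asd_dx9"), names(df))) {
      df[[col]] <- as.logical(df[[col]])
    }
    if ("asp_tscore" %in% names(df)) df$asp_tscore <- as.integer(df$asp_tscore)
  }
  validate_cohort(df)
  aw_log("read_cohort: %d records from %s", nrow(df), path)
  df
}

#' Write a cohort table to CSV/TSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells, dates are
#' ISO-8601, numeric precision is full double precision so the round trip is
#' lossless.
#'
#' @param cohort cohort data frame.
#' @param path output path; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort
  if ("dx_screen_date" %in% names(out)) {
    out$dx_screen_date <- format(out$dx_screen_date, "%Y-%m-%d")
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(out, path, sep = sep, na = "", row.names = FALSE,
                     quote = FALSE)
  aw_log("write_cohort: %d records to %s", nrow(cohort), path)
  invisible(path)
}

#' Serialize a stage result to JSON with provenance
#'
#' Embeds the run seed, a configuration fingerprint and the package version
#' so any result file can be traced to the run that produced it. Identical
#' inputs and seed give byte-identical files.
#'
#' @param results any stage output (lists, model fits, data frames).
#' @param path output `.json` path.
#' @param seed run seed recorded in the file.
#' @param config the [aroma_config()] the run used (hashed, not embedded).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, seed = NA_integer_,
                          config = aroma_config()) {
  payload <- list(
    meta = list(
      package = "aromawise",
      version = as.character(utils::packageVersion("aromawise")),
      seed = seed,
      config_hash = config_hash(config)
    ),
    results = strip_classes(results)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' Re-read a result file written by [write_results()]
#'
#' @param path `.json` path.
#' @return list with `meta` and `results`.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

## Recursively drop S3 classes so jsonlite serializes plainly.
strip_classes <- function(x) {
  if (is.data.frame(x)) {
    as.data.frame(lapply(x, function(col) {
      if (inherits(col, "Date")) format(col, "%Y-%m-%d") else col
    }), stringsAsFactors = FALSE, check.names = FALSE)
  } else if (is.list(x)) {
    lapply(unclass(x), strip_classes)
  } else if (inherits(x, "Date")) {
    format(x, "%Y-%m-%d")
  } else {
    x
  }
}
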