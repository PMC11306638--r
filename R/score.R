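#' Score definitions for CYP19A1 genetic aromatase activity
#'
#' Two published five-locus definitions are supported. The unweighted score
#' counts risk genotypes associated with lower estrogen levels (CC of
#' rs12148604, GG of rs4441215, CC of rs11632903, CC of rs752760, AA of
#' rs2445768); subjects carrying three or more are classified 'low aromatase
#' activity'. The weighted score sums aromatase-promoting allele counts
#' (0/1/2) across five eQTLs (A of rs7169770, C of rs1065778, A of
#' rs28757202, C of rs12917091, A of rs3784307), each weighted by its
#' normalized effect size (NES) in amygdala tissue; the sum is reversed so
#' higher means lower activity and the top quartile is classified low. NES
#' weights are not bundled: they are runtime configuration, and
#' [weighted_score_definition()] without weights uses a documented synthetic
#' placeholder set intended for tests only.
#'
#' @param loci data frame with columns `rsid`, `target` (risk genotype for
#'   the unweighted mode, promoting allele for the weighted mode) and
#'   `weight`.
#' @param mode `"unweighted_genotype"` or `"weighted_allele"`.
#' @param reverse negate the raw score before classification (used by the
#'   weighted score).
#' @param classify_rule `"count_ge_3"` or `"top_quartile"`.
#' @return a `score_definition` list.
#' @export
score_definition <- function(loci,
                             mode = c("unweighted_genotype", "weighted_allele"),
                             reverse = FALSE,
                             classify_rule = c("count_ge_3", "top_quartile")) {
  mode <- match.arg(mode)
  classify_rule <- match.arg(classify_rule)
  stopifnot(is.data.frame(loci), all(c("rsid", "target") %in% names(loci)))
  if (is.null(loci$weight)) loci$weight <- 1
  if (mode == "weighted_allele" && any(is.na(loci$weight) | loci$weight <= 0)) {
    bad <- loci$rsid[is.na(loci$weight) | loci$weight <= 0]
    stop("score_definition: missing or non-positive weight for locus ",
         paste(bad, collapse = ", "))
  }
  structure(list(loci = loci, mode = mode, reverse = reverse,
                 classify_rule = classify_rule),
            class = "score_definition")
}

#' @rdname score_definition
#' @export
unweighted_score_definition <- function() {
  score_definition(
    data.frame(
      rsid = c("rs12148604", "rs4441215", "rs11632903", "rs752760", "rs2445768"),
      target = c("CC", "GG", "CC", "CC", "AA"),
      weight = 1,
      stringsAsFactors = FALSE
    ),
    mode = "unweighted_genotype", reverse = FALSE, classify_rule = "count_ge_3"
  )
}

#' @rdname score_definition
#' @param weights named numeric NES weights, one per eQTL rsID. The default
#'   is a synthetic placeholder (NES values are an external resource); real
#'   analyses must supply their own.
#' @export
weighted_score_definition <- function(weights = NULL) {
  rsids <- c("rs7169770", "rs1065778", "rs28757202", "rs12917091", "rs3784307")
  if (is.null(weights)) {
    ## synthetic placeholder magnitudes, NES-like scale; tests only
    weights <- stats::setNames(c(0.55, 0.43, 0.38, 0.31, 0.24), rsids)
  }
  if (!all(rsids %in% names(weights))) {
    stop("weighted_score_definition: missing NES weight for locus ",
         paste(setdiff(rsids, names(weights)), collapse = ", "))
  }
  score_definition(
    data.frame(
      rsid = rsids,
      target = c("A", "C", "A", "C", "A"),
      weight = as.numeric(weights[rsids]),
      stringsAsFactors = FALSE
    ),
    mode = "weighted_allele", reverse = TRUE, classify_rule = "top_quartile"
  )
}

normalize_genotype <- function(g) {
  vapply(strsplit(g, ""), function(a) paste(sort(a), collapse = ""), character(1))
}

#' Unweighted genotype score for one subject
#'
#' @param genotypes named character vector, rsID -> genotype string.
#' @param definition a `score_definition` in unweighted mode.
#' @return list with `score` (0-5), `low_aromatase` (score >= 3) and
#'   `scoreable` (`FALSE` when any locus genotype is missing; such subjects
#'   are excluded downstream).
#' @export
unweighted_score <- function(genotypes, definition = unweighted_score_definition()) {
  stopifnot(definition$mode == "unweighted_genotype")
  g <- genotypes[definition$loci$rsid]
  if (anyNA(g) || length(g) < nrow(definition$loci)) {
    return(list(score = NA_integer_, low_aromatase = NA, scoreable = FALSE))
  }
  hits <- normalize_genotype(unname(g)) == normalize_genotype(definition$loci$target)
  score <- sum(hits)
  list(score = as.integer(score), low_aromatase = score >= 3, scoreable = TRUE)
}

#' Weighted eQTL allele score for one subject
#'
#' Raw score is the NES-weighted sum of promoting-allele counts; it is then
#' reversed (negated) so higher values mean lower predicted aromatase
#' activity. Classification against the cohort quartile is inclusive at the
#' boundary (`reversed >=` type-7 75th percentile), mirroring the inclusive
#' 'three or more' rule of the unweighted score.
#'
#' @param genotypes named character vector, rsID -> genotype string.
#' @param definition a `score_definition` in weighted mode.
#' @param cohort_scores reversed scores of the full cohort, used for the
#'   quartile cut; omit for raw scoring only.
#' @return list with `raw`, `score` (reversed), `low_aromatase` (or `NA`
#'   when `cohort_scores` absent) and `scoreable`.
#' @export
weighted_score <- function(genotypes, definition = weighted_score_definition(),
                           cohort_scores = NULL) {
  stopifnot(definition$mode == "weighted_allele")
  g <- genotypes[definition$loci$rsid]
  if (anyNA(g) || length(g) < nrow(definition$loci)) {
    return(list(raw = NA_real_, score = NA_real_, low_aromatase = NA,
                scoreable = FALSE))
  }
  counts <- mapply(function(geno, allele) {
    sum(strsplit(geno, "")[[1]] == allele)
  }, unname(g), definition$loci$target)
  raw <- sum(counts * definition$loci$weight)
  rev_score <- if (definition$reverse) -raw else raw
  low <- if (is.null(cohort_scores)) NA else {
    cut <- stats::quantile(cohort_scores, 0.75, type = 7, names = FALSE)
    ## tolerance keeps the boundary inclusive under weight rescaling
    rev_score >= cut - 1e-8 * max(1, abs(cut))
  }
  list(raw = raw, score = rev_score, low_aromatase = low, scoreable = TRUE)
}

#' Score every subject in a cohort
#'
#' Applies a score definition across the `geno_*` columns of a cohort table.
#' Unscoreable subjects (missing genotypes) are flagged and logged, never
#' silently dropped.
#'
#' @param cohort cohort data frame with `geno_<rsid>` columns.
#' @param definition a `score_definition`.
#' @return data frame: `subject_id`, `score`, `low_aromatase`, `scoreable`.
#' @export
aromatase_score <- function(cohort, definition = unweighted_score_definition()) {
  cols <- paste0("geno_", definition$loci$rsid)
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) stop("cohort lacks genotype columns: ", paste(miss, collapse = ", "))
  geno <- cohort[cols]
  scoreable <- !Reduce(`|`, lapply(geno, is.na))

  ## vectorized over subjects; unweighted_score()/weighted_score() remain the
  ## per-subject reference implementations (property-tested for agreement)
  norm2 <- function(v) {
    a1 <- substr(v, 1, 1); a2 <- substr(v, 2, 2)
    paste0(pmin(a1, a2), pmax(a1, a2))
  }
  if (definition$mode == "unweighted_genotype") {
    hits <- mapply(function(col, target) {
      as.integer(norm2(col) == norm2(target))
    }, geno, definition$loci$target)
    score <- as.integer(rowSums(hits))
    score[!scoreable] <- NA_integer_
    out <- data.frame(
      subject_id = cohort$subject_id,
      score = score,
      low_aromatase = score >= 3,
      scoreable = scoreable,
      stringsAsFactors = FALSE
    )
  } else {
    contrib <- mapply(function(col, allele, w) {
      ((substr(col, 1, 1) == allele) + (substr(col, 2, 2) == allele)) * w
    }, geno, definition$loci$target, definition$loci$weight)
    raw <- rowSums(contrib)
    score <- if (definition$reverse) -raw else raw
    score[!scoreable] <- NA_real_
    cut <- stats::quantile(score[scoreable], 0.75, type = 7, names = FALSE)
    out <- data.frame(
      subject_id = cohort$subject_id,
      score = score,
      ## boundary-inclusive with tolerance, robust to weight rescaling
      low_aromatase = score >= cut - 1e-8 * max(1, abs(cut)),
      scoreable = scoreable,
      stringsAsFactors = FALSE
    )
  }
  n_bad <- sum(!out$scoreable)
  if (n_bad > 0) aw_log("aromatase_score: %d of %d subjects unscoreable (missing genotypes)",
                        n_bad, nrow(out))
  out
}
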