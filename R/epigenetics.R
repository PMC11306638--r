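#' CpG promoter window
#'
#' A named, ordered set of CpG sites with 1-based genomic coordinates.
#' Windows are defined extensionally by their CpG ID list so annotation
#' drift cannot silently change membership; coordinates are carried for
#' reporting only.
#'
#' @param name window name.
#' @param cpg_ids ordered, nonempty character vector of CpG IDs.
#' @param chrom chromosome.
#' @param positions 1-based positions, strictly increasing, one per CpG.
#' @param role one of `"PII"`, `"PIf_7"`, `"PIf_15"`, `"composite"`,
#'   `"control"`.
#' @return a `methyl_window` list.
#' @export
methyl_window <- function(name, cpg_ids, chrom, positions,
                          role = c("PII", "PIf_7", "PIf_15", "composite",
                                   "control")) {
  role <- match.arg(role)
  stopifnot(length(cpg_ids) >= 1, length(positions) == length(cpg_ids))
  if (any(diff(positions) <= 0)) {
    stop("methyl_window: positions must be strictly increasing")
  }
  structure(list(name = name, cpg_ids = cpg_ids, chrom = chrom,
                 positions = as.numeric(positions), role = role),
            class = "methyl_window")
}

#' Default CYP19A1 promoter windows (synthetic placeholder membership)
#'
#' The published window memberships (2 CpGs on promoter PII, 7- and 15-CpG
#' windows over PI.f, and an upstream control window excluding both) are
#' shown only graphically in their source, so the bundled CpG IDs and
#' coordinates are a synthetic stand-in used by the cohort generator and the
#' test-suite. Real analyses should load their own definitions with
#' [read_methyl_windows()].
#'
#' @return named list of `methyl_window` objects: `pii`, `pif7`, `pif15`,
#'   `composite` (PII plus the 7-CpG PI.f window) and `control` (disjoint
#'   from both promoters).
#' @export
default_methyl_windows <- function() {
  pif_ids <- sprintf("cgPIF%02d", 1:15)
  pif_pos <- 51578000 + (1:15) * 120
  pii_ids <- sprintf("cgPII%02d", 1:2)
  pii_pos <- c(51630200, 51630360)
  ctl_ids <- sprintf("cgCTL%02d", 1:10)
  ctl_pos <- 51500000 + (1:10) * 600
  pif7_idx <- 5:11
  list(
    pii = methyl_window("PII", pii_ids, "chr15", pii_pos, "PII"),
    pif7 = methyl_window("PI.f_7", pif_ids[pif7_idx], "chr15",
                         pif_pos[pif7_idx], "PIf_7"),
    pif15 = methyl_window("PI.f_15", pif_ids, "chr15", pif_pos, "PIf_15"),
    composite = methyl_window("PI.f+PII", c(pif_ids[pif7_idx], pii_ids),
                              "chr15", c(pif_pos[pif7_idx], pii_pos),
                              "composite"),
    control = methyl_window("control", ctl_ids, "chr15", ctl_pos, "control")
  )
}

#' Read window definitions from a BED-like table plus a CpG map
#'
#' The window table is TSV with columns `chrom`, `start`, `end`, `name`,
#' `role`; the CpG map is TSV with columns `cpg_id`, `chrom`, `position`.
#' A window's members are the mapped CpGs whose position falls in
#' `[start, end]` (1-based inclusive), ordered by position.
#'
#' @param windows_path BED-like window TSV.
#' @param cpg_map_path CpG coordinate TSV.
#' @return named list of `methyl_window` objects.
#' @export
read_methyl_windows <- function(windows_path, cpg_map_path) {
  win <- utils::read.table(windows_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  map <- utils::read.table(cpg_map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "name", "role") %in% names(win)),
            all(c("cpg_id", "chrom", "position") %in% names(map)))
  out <- lapply(seq_len(nrow(win)), function(i) {
    m <- map[map$chrom == win$chrom[i] & map$position >= win$start[i] &
               map$position <= win$end[i], , drop = FALSE]
    m <- m[order(m$position), , drop = FALSE]
    if (nrow(m) == 0) stop("read_methyl_windows: window '", win$name[i],
                           "' contains no mapped CpGs")
    methyl_window(win$name[i], m$cpg_id, win$chrom[i], m$position,
                  role = win$role[i])
  })
  stats::setNames(out, win$name)
}

#' Per-subject average methylation over a window
#'
#' Arithmetic mean of the member CpG beta values. Subjects missing some
#' member CpGs are averaged over the rest (with a log entry); subjects
#' missing all members get `NA`.
#'
#' @param betas data frame or matrix of beta values, columns = CpG IDs.
#' @param window a `methyl_window`.
#' @return numeric vector of per-subject window means.
#' @export
window_mean <- function(betas, window) {
  present <- intersect(window$cpg_ids, colnames(betas))
  if (length(present) == 0) {
    stop("window_mean: none of the window CpGs are present in the data")
  }
  if (length(present) < length(window$cpg_ids)) {
    aw_log("window_mean: window '%s' missing %d of %d CpGs; averaging the rest",
           window$name, length(window$cpg_ids) - length(present),
           length(window$cpg_ids))
  }
  m <- as.matrix(betas[, present, drop = FALSE])
  out <- rowMeans(m, na.rm = TRUE)
  out[rowSums(!is.na(m)) == 0] <- NA_real_
  out
}

#' Association of window methylation with log2 exposure
#'
#' Ordinary least squares of window methylation in percentage points
#' (100 x mean beta) on `log2(BPA)` plus covariates. The exposure effect is
#' reported per log2 ug/L with a Wald 95% interval and two-sided p-value.
#' Below-LOD exposures must already be handled by the caller's LOD policy
#' (see [impute_below_lod()]).
#'
#' @param avg per-subject window mean beta values.
#' @param bpa exposure, ug/L (positive; already LOD-imputed).
#' @param covars optional data frame or matrix of adjustment covariates.
#' @param window_name label carried into the result.
#' @return list of class `aroma_window_assoc`: `window`, `effect`
#'   (pp per log2 ug/L), `ci`, `p`, `n`, `covariates_used`.
#' @export
window_association <- function(avg, bpa, covars = NULL, window_name = "window") {
  dat <- data.frame(y = 100 * avg, l2bpa = log2(bpa))
  cov_names <- character(0)
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    cov_names <- names(covars)
    dat <- cbind(dat, covars)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= ncol(dat) + 2) stop("window_association: too few complete cases")

  mm <- stats::model.matrix(~ ., dat[, -1, drop = FALSE])
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("window_association: collinear covariates: ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  est <- sm["l2bpa", "Estimate"]
  se <- sm["l2bpa", "Std. Error"]
  structure(list(
    window = window_name,
    effect = est,
    ci = est + c(-1, 1) * stats::qt(0.975, fit$df.residual) * se,
    p = sm["l2bpa", "Pr(>|t|)"],
    n = nrow(dat),
    covariates_used = cov_names
  ), class = "aroma_window_assoc")
}

#' @export
print.aroma_window_assoc <- function(x, ...) {
  cat(sprintf("%s: +%.4f pp per log2 ug/L (95%% CI %.4f, %.4f), p = %.3g, n = %d\n",
              x$window, x$effect, x$ci[1], x$ci[2], x$p, x$n))
  invisible(x)
}

#' Product-of-coefficients mediation with percentile bootstrap
#'
#' Linear-model mediation: `a` from `mediator ~ exposure + covars`, `b` and
#' the direct effect from `outcome ~ mediator + exposure + covars`;
#' `indirect = a * b`, `total = direct + indirect` (an exact OLS identity in
#' this no-interaction setting). Inference for the indirect effect is a
#' percentile bootstrap resampling subjects, with
#' `p = 2 * min(tail fractions crossing zero)` floored at `2 / n_boot`.
#'
#' @param exposure_cat 0/1 or logical exposure category.
#' @param mediator numeric mediator.
#' @param outcome numeric outcome.
#' @param covars optional data frame of adjustment covariates.
#' @param n_boot bootstrap replicates (warning below 200).
#' @param seed integer seed.
#' @return list of class `aroma_mediation`: `a_path`, `b_path`, `direct`,
#'   `indirect`, `total`, `boot_ci`, `p_indirect`, `n`, `n_boot`, `seed`.
#' @export
mediate <- function(exposure_cat, mediator, outcome, covars = NULL,
                    n_boot = 1000L, seed = 1L) {
  if (n_boot < 200) warning("mediate: fewer than 200 bootstrap replicates")
  x <- as.numeric(exposure_cat)
  dat <- data.frame(x = x, m = mediator, y = outcome)
  if (!is.null(covars)) dat <- cbind(dat, as.data.frame(covars))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 50) warning("mediate: fewer than 50 complete cases; bootstrap may be unstable")
  if (stats::var(dat$m) == 0) stop("mediate: mediator has zero variance")

  Z <- if (ncol(dat) > 3) as.matrix(dat[, -(1:3), drop = FALSE]) else NULL
  paths <- function(d, Zm) {
    Xm <- cbind(1, d$x, Zm)
    Xy <- cbind(1, d$m, d$x, Zm)
    a <- stats::lm.fit(Xm, d$m)$coefficients[2]
    cy <- stats::lm.fit(Xy, d$y)$coefficients
    c(a = unname(a), b = unname(cy[2]), direct = unname(cy[3]))
  }
  est <- paths(dat, Z)
  indirect <- est["a"] * est["b"]

  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, replace = TRUE)
      e <- paths(dat[idx, , drop = FALSE],
                 if (is.null(Z)) NULL else Z[idx, , drop = FALSE])
      e["a"] * e["b"]
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  p <- max(2 * min(mean(boots <= 0), mean(boots >= 0)), 2 / n_boot)
  structure(list(
    a_path = unname(est["a"]), b_path = unname(est["b"]),
    direct = unname(est["direct"]),
    indirect = unname(indirect),
    total = unname(est["direct"] + indirect),
    boot_ci = ci, p_indirect = p, n = n,
    n_boot = as.integer(n_boot), seed = as.integer(seed)
  ), class = "aroma_mediation")
}

#' @export
print.aroma_mediation <- function(x, ...) {
  cat(sprintf(
    "Mediation (n = %d): a = %.4f, b = %.4f\n  indirect = %.4f (95%% boot CI %.4f, %.4f; p = %.4g)\n  direct = %.4f, total = %.4f\n",
    x$n, x$a_path, x$b_path, x$indirect, x$boot_ci[1], x$boot_ci[2],
    x$p_indirect, x$direct, x$total))
  invisible(x)
}
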