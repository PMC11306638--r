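#' Miettinen's case-based population attributable fraction
#'
#' For a matched case-control design with a rare outcome, the attributable
#' fraction is estimated from the exposure prevalence among cases and the
#' odds ratio (as risk-ratio approximation): `pc * (or - 1) / or`.
#'
#' @param case_exposure_prev exposure prevalence among cases, in \[0, 1\].
#' @param or odds ratio (> 0).
#' @return attributable fraction (can be negative for protective exposure).
#' @export
paf_miettinen <- function(case_exposure_prev, or) {
  stopifnot(case_exposure_prev >= 0, case_exposure_prev <= 1)
  if (any(or <= 0)) stop("paf_miettinen: odds ratio must be positive")
  case_exposure_prev * (or - 1) / or
}

#' Attributable fraction with a set-level bootstrap interval
#'
#' Point estimate from [paf_miettinen()] on the observed case exposure
#' prevalence and the fitted conditional OR; percentile interval from
#' resampling whole matched sets with replacement and refitting, which
#' respects the matched design. Refit failures (e.g. a resample with no
#' informative sets) are dropped; more than 10% of them triggers a warning.
#'
#' @param sets matched-set data frame (`set_id`, `subject_id`, `role`).
#' @param exposure named logical vector of exposure flags, names = subject
#'   ids.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @return list of class `aroma_paf`: `paf`, `ci`, `case_exposure_prev`,
#'   `or_used`, `n_boot`, `n_failures`.
#' @export
paf_with_ci <- function(sets, exposure, n_boot = 2000L, seed = 1L) {
  dat <- sets
  dat$exposed <- as.logical(exposure[dat$subject_id])
  dat$case <- as.numeric(dat$role == "case")
  dat <- dat[!is.na(dat$exposed), , drop = FALSE]
  if (!any(dat$case == 1 & dat$exposed)) stop("paf_with_ci: no exposed cases")

  point_of <- function(d, or) {
    pc <- mean(d$exposed[d$case == 1])
    paf_miettinen(pc, or)
  }
  fit <- clr_fit(case ~ exposed, dat, sets = dat$set_id,
                 exposure = "exposedTRUE")
  if (fit$separation_flag || !is.finite(fit$or)) {
    stop("paf_with_ci: degenerate conditional fit (separation); OR not estimable")
  }
  point <- point_of(dat, fit$or)

  set_ids <- unique(dat$set_id)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(set_ids, replace = TRUE)
      parts <- lapply(seq_along(take), function(k) {
        d <- dat[dat$set_id == take[k], , drop = FALSE]
        d$set_id <- paste0(d$set_id, "_b", k)
        d
      })
      db <- do.call(rbind, parts)
      f <- tryCatch(clr_fit(case ~ exposed, db, sets = db$set_id,
                            exposure = "exposedTRUE"),
                    error = function(e) NULL)
      if (is.null(f) || f$separation_flag || !is.finite(f$or)) return(NA_real_)
      point_of(db, f$or)
    }, numeric(1))
  })
  fails <- sum(is.na(boots))
  if (fails > 0.1 * n_boot) {
    warning(sprintf("paf_with_ci: %d of %d bootstrap refits failed", fails, n_boot))
  }
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(paf = point, ci = ci,
                 case_exposure_prev = mean(dat$exposed[dat$case == 1]),
                 or_used = fit$or, n_boot = as.integer(n_boot),
                 n_failures = as.integer(fails)),
            class = "aroma_paf")
}

#' @export
print.aroma_paf <- function(x, ...) {
  cat(sprintf("PAF %.1f%% (95%% CI %.1f%%, %.1f%%); case exposure prevalence %.3f, OR %.3f\n",
              100 * x$paf, 100 * x$ci[1], 100 * x$ci[2],
              x$case_exposure_prev, x$or_used))
  invisible(x)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC is the Mann-Whitney probability that a random positive outscores a
#' random negative, ties counting one half; the 95% interval is DeLong's.
#'
#' @param scores numeric predictor.
#' @param labels logical (or 0/1) outcome; both classes must be present.
#' @return list: `auc`, `ci` (length 2), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2) stop("roc_auc: both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                 direction = "<", levels = c(FALSE, TRUE))
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  list(auc = as.numeric(pROC::auc(r)), ci = c(ci[1], ci[3]),
       n_pos = sum(labels), n_neg = sum(!labels))
}

#' Diagnostic likelihood ratios of a binary prediction
#'
#' `LR+ = sens / (1 - spec)`, `LR- = (1 - sens) / spec`. Zero and infinite
#' values are returned as-is, never continuity-corrected; an infinite LR+ is
#' additionally flagged.
#'
#' @param pred logical predicted-positive vector.
#' @param labels logical true-condition vector.
#' @return list: `lr_pos`, `lr_neg`, `sens`, `spec`, `lr_pos_infinite`.
#' @export
likelihood_ratios <- function(pred, labels) {
  pred <- as.logical(pred); labels <- as.logical(labels)
  keep <- !is.na(pred) & !is.na(labels)
  pred <- pred[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2) stop("likelihood_ratios: both classes must be present")
  sens <- mean(pred[labels])
  spec <- mean(!pred[!labels])
  lr_pos <- sens / (1 - spec)
  lr_neg <- (1 - sens) / spec
  list(lr_pos = lr_pos, lr_neg = lr_neg, sens = sens, spec = spec,
       lr_pos_infinite = is.infinite(lr_pos))
}
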