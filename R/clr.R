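## Conditional logistic regression for 1:m matched sets, fit from first
## principles by Newton-Raphson on the conditional log-likelihood
##   l(beta) = sum_s [ x_case' beta - log sum_{j in s} exp(x_j' beta) ].
## Each set contributes a multinomial term conditioning on its single case,
## which eliminates the per-set nuisance intercepts (matched-out
## confounding).

#' Fit a conditional logistic regression to matched sets
#'
#' The model is specified survival-style as `case ~ covariates` plus a set
#' identifier. The conditional likelihood is maximized by Newton-Raphson
#' with step-halving, starting at `beta = 0`, to gradient norm `1e-8`
#' (at most 50 iterations). Standard errors come from the inverse observed
#' information; the 95% interval on the OR scale is Wald,
#' `exp(beta +/- 1.96 se)`. Sets without within-set covariate variation are
#' uninformative and dropped (counted in `n_sets_dropped`). Separation —
#' `||beta||` drifting beyond 15 with a non-vanishing gradient — is flagged
#' and the estimates suppressed rather than repaired.
#'
#' @param formula model formula, response a 0/1 (or logical) case indicator.
#' @param data data frame with one row per subject in a matched set.
#' @param sets set identifiers: a column name in `data` or a vector of
#'   length `nrow(data)`. Exactly one case per set is required.
#' @param exposure name of the coefficient reported as `or`/`ci`; defaults
#'   to the first model term.
#' @return an object of class `aroma_clr` with elements `beta`, `se`,
#'   `vcov`, `or`, `ci`, `loglik`, `n_sets_informative`, `n_sets_dropped`,
#'   `converged`, `separation_flag`, `iterations`.
#' @examples
#' ## ten discordant pairs with the case exposed vs five the other way:
#' ## the conditional MLE is the discordant-pair ratio, OR = 2
#' pairs <- data.frame(
#'   set  = rep(1:15, each = 2),
#'   case = rep(c(1, 0), 15),
#'   x    = c(rep(c(1, 0), 10), rep(c(0, 1), 5))
#' )
#' clr_fit(case ~ x, pairs, sets = "set")
#' @export
clr_fit <- function(formula, data, sets, exposure = NULL) {
  if (is.character(sets) && length(sets) == 1) {
    if (!sets %in% names(data)) stop("clr_fit: no column '", sets, "' in data")
    sets <- data[[sets]]
  }
  stopifnot(length(sets) == nrow(data))
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  y <- as.numeric(y)
  X <- stats::model.matrix(stats::terms(formula), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) == 0) stop("clr_fit: model has no covariates")
  keep <- stats::complete.cases(X) & !is.na(y)
  if (any(!keep)) {
    aw_log("clr_fit: dropped %d rows with missing data", sum(!keep))
    X <- X[keep, , drop = FALSE]; y <- y[keep]; sets <- sets[keep]
  }
  set_f <- factor(sets)
  cases_per_set <- tapply(y, set_f, sum)
  if (any(cases_per_set != 1)) {
    stop("clr_fit: every set must contain exactly one case (after missing-data removal)")
  }

  ## drop sets with no within-set covariate variation: they contribute a
  ## constant to the likelihood and nothing to the score
  varies <- tapply(seq_along(y), set_f, function(idx) {
    any(apply(X[idx, , drop = FALSE], 2, function(col) length(unique(col)) > 1))
  })
  informative <- levels(set_f)[varies]
  n_dropped <- sum(!varies)
  if (length(informative) == 0) {
    stop("clr_fit: no informative sets (no within-set covariate variation)")
  }
  keep <- set_f %in% informative
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  set_f <- droplevels(set_f[keep])
  set_i <- as.integer(set_f)

  fit <- clr_newton(X, y, set_i)

  p <- ncol(X)
  coef_names <- colnames(X)
  exposure <- exposure %||% coef_names[1]
  if (!exposure %in% coef_names) {
    stop("clr_fit: exposure term '", exposure, "' not among coefficients")
  }
  beta <- stats::setNames(fit$beta, coef_names)
  se <- stats::setNames(fit$se, coef_names)
  suppressed <- fit$separation
  structure(list(
    call = match.call(),
    formula = formula,
    coef_names = coef_names,
    exposure = exposure,
    beta = if (suppressed) stats::setNames(rep(NA_real_, p), coef_names) else beta,
    se = if (suppressed) stats::setNames(rep(NA_real_, p), coef_names) else se,
    vcov = if (suppressed) matrix(NA_real_, p, p) else fit$vcov,
    or = if (suppressed) NA_real_ else unname(exp(beta[exposure])),
    ci = if (suppressed) c(NA_real_, NA_real_) else
      unname(exp(beta[exposure] + c(-1, 1) * 1.96 * se[exposure])),
    loglik = fit$loglik,
    n_sets_informative = length(informative),
    n_sets_dropped = n_dropped,
    n_subjects = length(y),
    converged = fit$converged,
    separation_flag = fit$separation,
    iterations = fit$iterations,
    X = X, y = y, set = set_i
  ), class = "aroma_clr")
}

## Newton-Raphson core on (X, y, set index); one case per set assumed.
clr_newton <- function(X, y, set_i, tol = 1e-8, max_iter = 50L) {
  p <- ncol(X)
  n_sets <- max(set_i)
  xc <- colSums(X[y == 1, , drop = FALSE])  # case covariate totals

  loglik_parts <- function(beta) {
    eta <- drop(X %*% beta)
    ## per-set log-sum-exp, stabilized
    set_max <- as.vector(tapply(eta, set_i, max))
    ee <- exp(eta - set_max[set_i])
    denom <- as.vector(rowsum(ee, set_i))
    w <- ee / denom[set_i]
    ll <- sum(eta[y == 1]) - sum(log(denom) + set_max)
    list(ll = ll, w = as.vector(w))
  }

  score_info <- function(w) {
    wX <- X * w
    g <- xc - colSums(wX)
    M <- rowsum(wX, set_i)                  # per-set weighted means (n_sets x p)
    H <- crossprod(X, wX) - crossprod(M)    # observed information
    list(g = g, H = H)
  }

  beta <- rep(0, p)
  parts <- loglik_parts(beta)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    si <- score_info(parts$w)
    gnorm <- sqrt(sum(si$g^2))
    if (gnorm < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(si$H, si$g), error = function(e) NULL)
    if (is.null(step)) { separation <- TRUE; break }
    ## step-halving on likelihood decrease
    new_beta <- beta + step
    new_parts <- loglik_parts(new_beta)
    halvings <- 0L
    while (new_parts$ll < parts$ll - 1e-12 && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new_parts <- loglik_parts(new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    parts <- new_parts
    if (sqrt(sum(beta^2)) > 15) {
      si2 <- score_info(parts$w)
      if (sqrt(sum(si2$g^2)) > tol) { separation <- TRUE; break }
    }
  }
  if (!converged && !separation) {
    si <- score_info(parts$w)
    if (sqrt(sum(si$g^2)) < tol) converged <- TRUE
  }
  si <- score_info(parts$w)
  vc <- tryCatch(solve(si$H), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, se = sqrt(pmax(diag(vc), 0)), vcov = vc,
       loglik = parts$ll, converged = converged && !separation,
       separation = separation, iterations = iter)
}

#' @export
print.aroma_clr <- function(x, digits = 4, ...) {
  cat("Conditional logistic regression (1 case per matched set)\n")
  cat(sprintf("  informative sets: %d (dropped %d concordant)\n",
              x$n_sets_informative, x$n_sets_dropped))
  if (x$separation_flag) {
    cat("  separation detected; estimates suppressed\n")
    return(invisible(x))
  }
  cat(sprintf("  %s: OR %.3f (95%% CI %.3f, %.3f)\n",
              x$exposure, x$or, x$ci[1], x$ci[2]))
  cat(sprintf("  log-likelihood %.4f, converged: %s (%d iterations)\n",
              x$loglik, x$converged, x$iterations))
  invisible(x)
}

#' @export
summary.aroma_clr <- function(object, ...) {
  z <- object$beta / object$se
  tab <- cbind(
    coef = object$beta, `exp(coef)` = exp(object$beta), se = object$se,
    z = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z))
  )
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.aroma_clr"
  out
}

#' @export
print.summary.aroma_clr <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.aroma_clr <- function(object, ...) object$beta

#' @export
vcov.aroma_clr <- function(object, ...) object$vcov

#' @export
logLik.aroma_clr <- function(object, ...) {
  structure(object$loglik, df = length(object$beta), class = "logLik")
}

#' @export
confint.aroma_clr <- function(object, parm, level = 0.95, ...) {
  if (missing(parm)) parm <- object$coef_names
  q <- stats::qnorm(1 - (1 - level) / 2)
  lo <- object$beta[parm] - q * object$se[parm]
  hi <- object$beta[parm] + q * object$se[parm]
  out <- cbind(lo, hi)
  colnames(out) <- sprintf("%g %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' Within-set case probabilities from a fitted conditional model
#'
#' @param object an `aroma_clr` fit.
#' @param type `"prob"` for the conditional probability each subject is the
#'   set's case, `"lp"` for the linear predictor.
#' @param ... unused.
#' @return numeric vector aligned with the rows used in the fit.
#' @export
predict.aroma_clr <- function(object, type = c("prob", "lp"), ...) {
  type <- match.arg(type)
  if (object$separation_flag) stop("predict: estimates suppressed (separation)")
  eta <- drop(object$X %*% object$beta)
  if (type == "lp") return(eta)
  mx <- tapply(eta, object$set, max)[object$set]
  ee <- exp(eta - mx)
  as.vector(ee / rowsum(ee, object$set)[object$set])
}

#' @export
residuals.aroma_clr <- function(object, ...) {
  object$y - predict(object, type = "prob")
}

#' Sex-by-aromatase-score stratified exposure analysis
#'
#' Runs the full subgroup chain on a cohort: dichotomize exposure at the
#' configured quantile, score and classify aromatase activity, and within
#' each (sex x low/high aromatase) cell build matched sets (on ancestry and
#' urine collection time, nearest screen date/age) and fit the conditional
#' model of high exposure on the outcome. Cells with fewer than
#' `min_exposed_cases` exposed cases are skipped with a recorded reason
#' rather than fit.
#'
#' @param cohort cohort data frame.
#' @param config an [aroma_config()].
#' @param definition score definition (default unweighted five-SNP score).
#' @param outcome logical outcome column (default `"asd_dx9"`).
#' @param min_exposed_cases sparse-cell threshold (default 3).
#' @return named list, one entry per `sex:aromatase` cell: either an
#'   `aroma_clr` fit or a list with `skipped = TRUE` and a `reason`.
#' @export
stratified_interaction_analysis <- function(cohort, config = aroma_config(),
                                            definition = unweighted_score_definition(),
                                            outcome = "asd_dx9",
                                            min_exposed_cases = 3L) {
  dich <- dichotomize_exposure(cohort$bpa_raw, config$exposure_quantile)
  scores <- aromatase_score(cohort, definition)
  cohort$high_bpa <- dich$high
  cohort$low_aromatase <- scores$low_aromatase[match(cohort$subject_id,
                                                     scores$subject_id)]
  cells <- expand.grid(sex = c("male", "female"),
                       low_aromatase = c(TRUE, FALSE),
                       stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sx <- cells$sex[i]; lw <- cells$low_aromatase[i]
    lab <- sprintf("%s:%s", sx, if (lw) "low" else "high")
    sub <- cohort[!is.na(cohort$low_aromatase) & cohort$sex == sx &
                    cohort$low_aromatase == lw & !is.na(cohort$high_bpa) &
                    !is.na(cohort[[outcome]]), , drop = FALSE]
    n_exp_cases <- sum(sub$high_bpa & sub[[outcome]])
    if (n_exp_cases < min_exposed_cases) {
      aw_log("stratified analysis: cell %s skipped (%d exposed cases < %d)",
             lab, n_exp_cases, min_exposed_cases)
      out[[lab]] <- list(skipped = TRUE,
                         reason = sprintf("only %d exposed cases", n_exp_cases),
                         n_exposed_cases = n_exp_cases)
      next
    }
    sets <- matched_design(sub, stratum_vars = c("ancestry_caucasian4",
                                                 "urine_time_pm"),
                           outcome = outcome, m = config$match_m,
                           seed = stage_seed(config$seed, paste0("match-", lab)))
    dat <- merge(sets, sub[, c("subject_id", "high_bpa", outcome)],
                 by = "subject_id", sort = FALSE)
    dat$case <- as.numeric(dat$role == "case")
    fit <- tryCatch(
      clr_fit(case ~ high_bpa, dat, sets = dat$set_id, exposure = "high_bpaTRUE"),
      error = function(e) list(skipped = TRUE, reason = conditionMessage(e)))
    if (inherits(fit, "aroma_clr")) fit$design <- sets
    out[[lab]] <- fit
  }
  out
}
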