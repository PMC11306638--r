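test_that("1:1 binary-exposure fits equal the discordant-pair closed form", {
  dat <- make_pairs(n10 = 10, n01 = 5, n_conc_exposed = 7, n_conc_unexposed = 4)
  fit <- quiet(clr_fit(case ~ x, dat, sets = "set"))
  expect_equal(fit$or, 2.0, tolerance = 1e-8)
  expect_equal(fit$n_sets_informative, 15)   # concordant pairs dropped
  expect_equal(fit$n_sets_dropped, 11)

  ## arbitrary random discordant counts
  set.seed(13)
  for (i in 1:20) {
    n10 <- sample(1:30, 1); n01 <- sample(1:30, 1)
    d <- make_pairs(n10, n01, sample(0:5, 1))
    f <- quiet(clr_fit(case ~ x, d, sets = "set"))
    expect_equal(f$or, n10 / n01, tolerance = 1e-6)
    ## Wald SE of the log OR of discordant pairs: sqrt(1/n10 + 1/n01)
    expect_equal(unname(f$se), sqrt(1 / n10 + 1 / n01), tolerance = 1e-6)
  }
})

test_that("all-concordant designs raise the zero-information error", {
  dat <- make_pairs(0, 0, n_conc_exposed = 6, n_conc_unexposed = 6)
  expect_error(quiet(clr_fit(case ~ x, dat, sets = "set")), "informative")
})

test_that("estimates match brute-force likelihood maximization on 1:m sets", {
  set.seed(17)
  for (m in c(2, 4, 8)) {
    dat <- random_design(n_sets = 25, m = m, beta = 0.9)
    fit <- quiet(clr_fit(case ~ x, dat, sets = "set"))
    bhat <- oracle_clr_grid(dat)
    expect_equal(unname(coef(fit)), bhat, tolerance = 1e-4)
    ## the oracle likelihood at the fitted point is the maximum
    expect_gte(oracle_clr_loglik(coef(fit), dat) + 1e-8,
               oracle_clr_loglik(bhat, dat))
  }
})

test_that("a fixed 1:2 set maximizes the printed conditional likelihood", {
  dat <- data.frame(set = c(1, 1, 1, 2, 2, 2, 3, 3, 3),
                    case = c(1, 0, 0, 1, 0, 0, 0, 1, 0),
                    x = c(1.2, 0.1, -0.5, 0.7, 0.9, -1.1, 0.0, 0.4, 1.6))
  fit <- quiet(clr_fit(case ~ x, dat, sets = "set"))
  expect_equal(unname(coef(fit)), oracle_clr_grid(dat), tolerance = 1e-4)
  expect_equal(fit$loglik, oracle_clr_loglik(coef(fit), dat), tolerance = 1e-10)
})

test_that("the engine agrees with an independent conditional-likelihood fitter", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  set.seed(19)
  for (i in 1:5) {
    dat <- do.call(rbind, lapply(1:40, function(s) {
      k <- sample(2:6, 1)
      x1 <- rbinom(k, 1, 0.4); x2 <- rnorm(k)
      pr <- exp(0.8 * x1 + 0.5 * x2); pr <- pr / sum(pr)
      case <- rmultinom(1, 1, pr)[, 1]
      data.frame(set = s, case = case, x1 = x1, x2 = x2)
    }))
    mine <- quiet(clr_fit(case ~ x1 + x2, dat, sets = "set"))
    ref <- clogit(case ~ x1 + x2 + strata(set), data = dat)
    expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
    expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  }
})

test_that("within-set constant shifts leave the fit unchanged (matched-out confounding)", {
  set.seed(23)
  dat <- random_design(n_sets = 30, m = 3, beta = 0.6)
  dat$x <- dat$x + rnorm(nrow(dat), sd = 0.2)  # make x continuous
  f1 <- quiet(clr_fit(case ~ x, dat, sets = "set"))
  shifted <- dat
  shifts <- rnorm(30, sd = 5)
  shifted$x <- shifted$x + shifts[shifted$set]
  f2 <- quiet(clr_fit(case ~ x, shifted, sets = "set"))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$se, f2$se, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("first-order conditions hold at the optimum", {
  set.seed(29)
  dat <- random_design(n_sets = 50, m = 4, beta = 0.5)
  fit <- quiet(clr_fit(case ~ x, dat, sets = "set"))
  expect_true(fit$converged)
  expect_lte(fit$loglik, 0)
  ## numeric gradient near zero, numeric curvature negative
  eps <- 1e-5
  g <- (oracle_clr_loglik(coef(fit) + eps, dat) -
          oracle_clr_loglik(coef(fit) - eps, dat)) / (2 * eps)
  expect_lt(abs(g), 1e-4)
  expect_true(all(eigen(solve(vcov(fit)))$values > 0))
  expect_true(fit$ci[1] <= fit$or && fit$or <= fit$ci[2])
})

test_that("separation is flagged and estimates suppressed, not repaired", {
  ## every case exposed, every control unexposed: the MLE diverges
  dat <- do.call(rbind, lapply(1:10, function(s) {
    data.frame(set = s, case = c(1, 0, 0), x = c(1, 0, 0))
  }))
  fit <- quiet(clr_fit(case ~ x, dat, sets = "set"))
  expect_true(fit$separation_flag)
  expect_false(fit$converged)
  expect_true(is.na(fit$or))
  expect_true(all(is.na(fit$beta)))
})

test_that("conditional case probabilities sum to one per set and drive residuals", {
  set.seed(31)
  dat <- random_design(n_sets = 20, m = 3, beta = 0.8)
  fit <- quiet(clr_fit(case ~ x, dat, sets = "set"))
  p <- predict(fit, type = "prob")
  sums <- as.vector(tapply(p, fit$set, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-10)
  r <- residuals(fit)
  expect_equal(r, fit$y - p, tolerance = 1e-12)
  expect_equal(sum(p), fit$n_sets_informative, tolerance = 1e-8)
})

test_that("sets violating the one-case rule are rejected", {
  dat <- data.frame(set = c(1, 1, 2, 2), case = c(1, 1, 1, 0), x = c(1, 0, 1, 0))
  expect_error(quiet(clr_fit(case ~ x, dat, sets = "set")), "exactly one case")
})

test_that("stratified subgroup analysis fits the target cell and skips sparse cells", {
  coh <- quiet(generate_cohort(sim_scenario(n_subjects = 2500, seed = 71)))
  cfg <- aroma_config(seed = 71)
  res <- quiet(stratified_interaction_analysis(coh, cfg))
  expect_setequal(names(res),
                  c("male:low", "male:high", "female:low", "female:high"))
  ml <- res[["male:low"]]
  expect_s3_class(ml, "aroma_clr")
  expect_gt(ml$or, 1)

  ## force sparseness: a cohort with almost no cases
  tiny <- quiet(generate_cohort(sim_scenario(n_subjects = 250, seed = 72)))
  res2 <- quiet(stratified_interaction_analysis(tiny, aroma_config(seed = 72)))
  skipped <- Filter(function(r) isTRUE(r$skipped), res2)
  expect_gt(length(skipped), 0)
  expect_true(all(vapply(skipped, function(r) nzchar(r$reason), logical(1))))
})

test_that("print and summary methods render without error", {
  dat <- make_pairs(8, 4)
  fit <- quiet(clr_fit(case ~ x, dat, sets = "set"))
  expect_output(print(fit), "OR 2")
  expect_output(print(summary(fit)), "Coefficients")
  expect_s3_class(logLik(fit), "logLik")
  ci <- confint(fit)
  expect_equal(unname(exp(ci[1, ])), fit$ci, tolerance = 1e-3)
})
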