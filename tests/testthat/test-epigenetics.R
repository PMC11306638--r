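test_that("window construction enforces its invariants", {
  expect_error(methyl_window("w", c("a", "b"), "chr15", c(10, 10), "control"),
               "strictly increasing")
  expect_error(methyl_window("w", character(0), "chr15", numeric(0), "PII"))
  w <- default_methyl_windows()
  expect_setequal(w$composite$cpg_ids, union(w$pii$cpg_ids, w$pif7$cpg_ids))
  expect_length(intersect(w$control$cpg_ids,
                          c(w$pif15$cpg_ids, w$pii$cpg_ids)), 0)
  expect_length(w$pii$cpg_ids, 2)
  expect_length(w$pif7$cpg_ids, 7)
  expect_length(w$pif15$cpg_ids, 15)
  expect_true(all(w$pif7$cpg_ids %in% w$pif15$cpg_ids))
})

test_that("BED-like definitions reproduce window membership exactly", {
  wpath <- system.file("extdata", "cyp19a1_windows_synthetic.tsv",
                       package = "aromawise")
  mpath <- system.file("extdata", "cyp19a1_cpg_map_synthetic.tsv",
                       package = "aromawise")
  loaded <- read_methyl_windows(wpath, mpath)
  ref <- default_methyl_windows()
  expect_identical(loaded$PII$cpg_ids, ref$pii$cpg_ids)
  expect_identical(loaded$`PI.f_7`$cpg_ids, ref$pif7$cpg_ids)
  expect_identical(loaded$`PI.f_15`$cpg_ids, ref$pif15$cpg_ids)
  expect_identical(loaded$control$cpg_ids, ref$control$cpg_ids)
  expect_identical(loaded$PII$positions, ref$pii$positions)
})

test_that("window means average member CpGs and tolerate partial missingness", {
  w <- methyl_window("w", c("cgA", "cgB"), "chr1", c(1, 2), "control")
  betas <- data.frame(cgA = c(0.5, 0.2, NA, NA), cgB = c(0.5, 0.4, 0.6, NA))
  m <- quiet(window_mean(betas, w))
  expect_equal(m, c(0.5, 0.3, 0.6, NA))
  one <- methyl_window("one", "cgB", "chr1", 2, "control")
  expect_equal(window_mean(betas, one), betas$cgB)
  none <- methyl_window("none", "cgZ", "chr1", 3, "control")
  expect_error(window_mean(betas, none), "none of the window CpGs")
})

test_that("covariate-free association equals the closed-form regression slope", {
  avg <- c(0.10, 0.11, 0.12, 0.105, 0.118, 0.126)
  bpa <- c(0.5, 1, 2, 0.8, 3, 6)
  x <- log2(bpa); y <- 100 * avg
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fit <- window_association(avg, bpa, window_name = "fix")
  expect_equal(fit$effect, slope, tolerance = 1e-10)
  expect_true(fit$ci[1] <= fit$effect && fit$effect <= fit$ci[2])
  expect_equal(fit$n, 6)
})

test_that("collinear covariates are rejected by name", {
  set.seed(47)
  avg <- runif(30, 0.1, 0.2); bpa <- rlnorm(30)
  covars <- data.frame(a = rnorm(30))
  covars$b <- 2 * covars$a
  expect_error(window_association(avg, bpa, covars), "collinear.*b")
})

test_that("the association recovers an injected slope and is null under permutation", {
  set.seed(53)
  sc <- sim_scenario(n_subjects = 800, seed = 53)
  w <- default_methyl_windows()
  ests <- p_null <- numeric(30)
  for (i in 1:30) {
    coh <- quiet(generate_cohort(sim_scenario(n_subjects = 800, seed = 530 + i)))
    avg <- window_mean(coh[grep("^cg", names(coh))], w$pif7)
    fit <- window_association(avg, coh$bpa_true, window_name = "PI.f_7")
    ests[i] <- fit$effect
    perm <- window_association(sample(avg), coh$bpa_true)
    p_null[i] <- perm$p
  }
  expect_lt(abs(mean(ests) - sc$meth_slope_per_log2), 0.01)
  ## permutation-null p-values roughly uniform
  expect_gt(mean(p_null > 0.05), 0.7)
  expect_lt(mean(p_null < 0.05), 0.3)
})

test_that("the composite-window effect is the pooled-mean regression, not an average of effects", {
  coh <- quiet(generate_cohort(sim_scenario(n_subjects = 600, seed = 59)))
  w <- default_methyl_windows()
  betas <- coh[grep("^cg", names(coh))]
  pooled <- window_mean(betas, w$composite)
  fit_pooled <- window_association(pooled, coh$bpa_true, window_name = "composite")
  f_pii <- window_association(window_mean(betas, w$pii), coh$bpa_true)
  f_pif <- window_association(window_mean(betas, w$pif7), coh$bpa_true)
  ## equals the regression on the pooled average by construction...
  manual <- window_association(rowMeans(betas[w$composite$cpg_ids]),
                               coh$bpa_true)
  expect_equal(fit_pooled$effect, manual$effect, tolerance = 1e-12)
  ## ...and is not in general the mean of the two window effects
  expect_false(isTRUE(all.equal(fit_pooled$effect,
                                mean(c(f_pii$effect, f_pif$effect)),
                                tolerance = 1e-6)))
})

test_that("mediation obeys the exact OLS decomposition and is seed-stable", {
  set.seed(61)
  n <- 200
  x <- rbinom(n, 1, 0.3)
  m <- 0.5 * x + rnorm(n, 0, 0.4)
  y <- 0.4 * m + 0.2 * x + rnorm(n, 0, 0.4)
  covars <- data.frame(z = rnorm(n))
  med <- quiet(mediate(x, m, y, covars, n_boot = 300, seed = 9))
  ## total = direct + indirect equals the mediator-free exposure coefficient
  total_fit <- lm(y ~ x + z, data = data.frame(y = y, x = x, z = covars$z))
  expect_equal(med$total, unname(coef(total_fit)["x"]), tolerance = 1e-10)
  expect_equal(med$indirect, med$a_path * med$b_path, tolerance = 1e-12)

  med2 <- quiet(mediate(x, m, y, covars, n_boot = 300, seed = 9))
  expect_equal(med$boot_ci, med2$boot_ci)
  expect_equal(med$p_indirect, med2$p_indirect)
  expect_gte(med$p_indirect, 2 / 300)

  expect_error(quiet(mediate(x, rep(1, n), y, n_boot = 300, seed = 1)),
               "zero variance")
  expect_warning(quiet_m <- suppressMessages(mediate(x, m, y, n_boot = 100,
                                                     seed = 1)),
                 "200")
})

test_that("indirect-effect p-values are approximately uniform under the b = 0 null", {
  ## exposure moves the mediator (a != 0) but the mediator does not move the
  ## outcome: the indirect effect is zero and its bootstrap p should be
  ## close to uniform (the complete a = b = 0 null is known-conservative
  ## for product-of-coefficients tests and is not the reference here)
  ps <- vapply(1:200, function(i) {
    n <- 300
    x <- rbinom(n, 1, 0.3)
    m <- 0.5 * x + rnorm(n, 0, 0.15)
    y <- rnorm(n, 0, 0.15)
    quiet(mediate(x, m, y, n_boot = 200, seed = 7000 + i))$p_indirect
  }, numeric(1))
  ks <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(ks, 0.1)
})

test_that("a null mediator path gives an indirect effect near zero with honest coverage", {
  set.seed(67)
  cover <- logical(20)
  for (i in 1:20) {
    n <- 300
    x <- rbinom(n, 1, 0.3)
    m <- 0.5 * x + rnorm(n, 0, 0.3)
    y <- 0 * m + rnorm(n, 0, 0.3)      # b = 0: no mediation
    med <- quiet(mediate(x, m, y, n_boot = 300, seed = i))
    cover[i] <- med$boot_ci[1] <= 0 && 0 <= med$boot_ci[2]
  }
  expect_gte(mean(cover), 0.8)
})
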