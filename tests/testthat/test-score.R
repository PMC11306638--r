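risk_genos <- c(rs12148604 = "CC", rs4441215 = "GG", rs11632903 = "CC",
                rs752760 = "CC", rs2445768 = "AA")

test_that("the unweighted five-genotype score counts risk genotypes", {
  full <- unweighted_score(risk_genos)
  expect_equal(full$score, 5L)
  expect_true(full$low_aromatase)

  three <- risk_genos
  three["rs752760"] <- "TT"; three["rs2445768"] <- "GG"
  r3 <- unweighted_score(three)
  expect_equal(r3$score, 3L)
  expect_true(r3$low_aromatase)   # 'three or more' is low

  none <- c(rs12148604 = "CT", rs4441215 = "GA", rs11632903 = "TT",
            rs752760 = "TT", rs2445768 = "GG")
  r0 <- unweighted_score(none)
  expect_equal(r0$score, 0L)
  expect_false(r0$low_aromatase)

  two <- three; two["rs11632903"] <- "CT"
  expect_false(unweighted_score(two)$low_aromatase)

  ## allele order within a genotype string does not matter
  expect_equal(unweighted_score(replace(risk_genos, 1, "CC"))$score,
               unweighted_score(risk_genos)$score)
})

test_that("missing genotypes flag the subject unscoreable", {
  g <- risk_genos; g["rs4441215"] <- NA
  r <- unweighted_score(g)
  expect_false(r$scoreable)
  expect_true(is.na(r$score))
  r2 <- weighted_score(c(rs7169770 = "AA"), weighted_score_definition())
  expect_false(r2$scoreable)
})

test_that("the weighted eQTL score is the NES-weighted allele count, reversed", {
  w <- setNames(c(0.5, 0.3, 0.2, 0.4, 0.1),
                c("rs7169770", "rs1065778", "rs28757202", "rs12917091",
                  "rs3784307"))
  def <- weighted_score_definition(w)
  ## promoting allele counts 2, 1, 0, 0, 1
  g <- c(rs7169770 = "AA", rs1065778 = "CT", rs28757202 = "GG",
         rs12917091 = "TT", rs3784307 = "AG")
  r <- weighted_score(g, def)
  expect_equal(r$raw, 2 * 0.5 + 1 * 0.3 + 0 + 0 + 1 * 0.1)
  expect_equal(r$score, -1.4)

  zero <- c(rs7169770 = "GG", rs1065778 = "TT", rs28757202 = "GG",
            rs12917091 = "TT", rs3784307 = "GG")
  expect_equal(weighted_score(zero, def)$raw, 0)

  ## quartile classification against supplied cohort scores, inclusive at
  ## the boundary (type-7 75th percentile of these is exactly -1.4)
  cohort_scores <- c(-3, -2, -1.4, -1.4)
  expect_true(weighted_score(g, def, cohort_scores)$low_aromatase)
  expect_false(weighted_score(g, def, c(-3, -1.2, -1.1, -1))$low_aromatase)
})

test_that("weight configuration is validated per locus", {
  expect_error(weighted_score_definition(c(rs7169770 = 0.5)), "rs1065778")
  expect_error(score_definition(
    data.frame(rsid = "rs1", target = "A", weight = -1),
    mode = "weighted_allele"), "rs1")
})

test_that("adding risk genotypes or promoting alleles never lowers the score", {
  set.seed(7)
  def <- weighted_score_definition()
  for (i in 1:25) {
    ## random genotypes, then upgrade one locus toward the target
    g <- vapply(seq_len(5), function(j) {
      paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE), collapse = "")
    }, character(1))
    names(g) <- def$loci$rsid
    j <- sample(5, 1)
    promoted <- g
    promoted[j] <- paste0(def$loci$target[j],
                          substr(g[j], 2, 2))
    expect_gte(weighted_score(promoted, def)$raw,
               weighted_score(g, def)$raw)
  }
})

test_that("classification is invariant to rescaling all weights", {
  coh <- quiet(generate_cohort(sim_scenario(n_subjects = 400, seed = 51)))
  w1 <- setNames(c(0.55, 0.43, 0.38, 0.31, 0.24),
                 weighted_score_definition()$loci$rsid)
  s1 <- aromatase_score(coh, weighted_score_definition(w1))
  s2 <- aromatase_score(coh, weighted_score_definition(w1 * 7.3))
  expect_identical(s1$low_aromatase, s2$low_aromatase)
})

test_that("equal weights reduce the weighted ranking to the allele count", {
  coh <- quiet(generate_cohort(sim_scenario(n_subjects = 200, seed = 52)))
  def_eq <- weighted_score_definition(
    setNames(rep(1, 5), weighted_score_definition()$loci$rsid))
  s <- aromatase_score(coh, def_eq)
  counts <- rowSums(sapply(seq_len(5), function(j) {
    col <- coh[[paste0("geno_", def_eq$loci$rsid[j])]]
    (substr(col, 1, 1) == def_eq$loci$target[j]) +
      (substr(col, 2, 2) == def_eq$loci$target[j])
  }))
  expect_equal(order(s$score), order(-counts))
})

test_that("about a quarter of a synthetic cohort is classified low aromatase", {
  coh <- quiet(generate_cohort(sim_scenario(n_subjects = 4000, seed = 53)))
  su <- aromatase_score(coh, unweighted_score_definition())
  expect_lt(abs(mean(su$low_aromatase) - 0.25), 0.04)
  sw <- aromatase_score(coh, weighted_score_definition())
  expect_lt(abs(mean(sw$low_aromatase) - 0.25), 0.06)
})

test_that("cohort scoring agrees with the per-subject reference operations", {
  coh <- quiet(generate_cohort(sim_scenario(n_subjects = 60, seed = 54)))
  udef <- unweighted_score_definition()
  su <- aromatase_score(coh, udef)
  for (i in c(1, 17, 42)) {
    g <- vapply(udef$loci$rsid, function(r) coh[[paste0("geno_", r)]][i],
                character(1))
    expect_equal(su$score[i], unweighted_score(g, udef)$score)
  }
  wdef <- weighted_score_definition()
  sw <- aromatase_score(coh, wdef)
  for (i in c(2, 23, 55)) {
    g <- vapply(wdef$loci$rsid, function(r) coh[[paste0("geno_", r)]][i],
                character(1))
    expect_equal(sw$score[i], weighted_score(g, wdef)$score)
  }
})
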