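#' Simulation scenario for synthetic cohorts
#'
#' Defines the statistical structure of a generated birth cohort. The
#' defaults emulate the study conditions the analysis chain assumes:
#' a right-skewed urinary BPA distribution (lognormal with median 0.68 ug/L
#' and 75th percentile 2.18 ug/L), an assay LOD of 0.57 ug/L leaving ~46%
#' of measures left-censored, ~21% of subjects without a BPA measure, a
#' five-SNP genetic score whose 'low aromatase' class covers ~25% of the
#' cohort, an ASD outcome of ~4% prevalence concentrated in boys (~2.1:1),
#' an exposure odds ratio of 3.5 confined to the (male, low-aromatase)
#' stratum, an ASP-above-median fraction of 36.8%, promoter methylation
#' rising 0.05 percentage points per log2 ug/L BPA, and an
#' exposure -> aromatase-methylation -> BDNF-methylation mediation chain
#' with path coefficients a = 0.5 and b = 0.4.
#'
#' @param n_subjects cohort size.
#' @param prop_male fraction male.
#' @param prop_ancestry fraction with all four grandparents Caucasian.
#' @param prop_urine_pm fraction of maternal urines collected after 2 pm.
#' @param bpa_logmean,bpa_logsd log-scale parameters of the exposure
#'   lognormal.
#' @param lod assay limit of detection, ug/L.
#' @param frac_bpa_missing fraction of subjects without a BPA measure.
#' @param frac_asp_missing fraction without a CBCL ASP score.
#' @param interaction_or true exposure odds ratio within the (male,
#'   low-aromatase) stratum.
#' @param baseline_or true exposure OR in all other strata.
#' @param male_or odds multiplier for male sex on the outcome.
#' @param outcome_prevalence marginal ASD prevalence.
#' @param asp_high_prev marginal fraction with ASP T-score above 50.
#' @param asp_asd_or odds multiplier linking diagnosed ASD to a high ASP
#'   score (drives the ASP->diagnosis predictiveness).
#' @param risk_allele_freqs named allele frequencies for the five unweighted
#'   score SNPs (risk genotype = homozygous risk allele under HWE).
#' @param eqtl_allele_freqs named promoting-allele frequencies for the five
#'   eQTLs of the weighted score.
#' @param meth_slope_per_log2 promoter methylation slope, percentage points
#'   per log2 ug/L BPA.
#' @param noise_sd_meth per-CpG beta-scale noise SD.
#' @param mediation_a exposure-category -> mediator path coefficient.
#' @param mediation_b mediator -> outcome-methylation path coefficient.
#' @param mediation_direct direct exposure-category -> outcome-methylation
#'   path.
#' @param mediation_noise_sd noise SD of the mediator and outcome equations.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(n_subjects = 1074L,
                         prop_male = 0.52,
                         prop_ancestry = 0.80,
                         prop_urine_pm = 0.50,
                         bpa_logmean = log(0.68),
                         bpa_logsd = (log(2.18) - log(0.68)) / stats::qnorm(0.75),
                         lod = 0.57,
                         frac_bpa_missing = 0.21,
                         frac_asp_missing = 0.37,
                         interaction_or = 3.5,
                         baseline_or = 1.0,
                         male_or = 1.65,
                         outcome_prevalence = 0.04,
                         asp_high_prev = 0.368,
                         asp_asd_or = 12,
                         risk_allele_freqs = NULL,
                         eqtl_allele_freqs = NULL,
                         meth_slope_per_log2 = 0.05,
                         noise_sd_meth = 0.01,
                         mediation_a = 0.5,
                         mediation_b = 0.4,
                         mediation_direct = 0,
                         mediation_noise_sd = 0.15,
                         seed = 20260101L) {
  udef <- unweighted_score_definition()
  wdef <- weighted_score_definition()
  if (is.null(risk_allele_freqs)) {
    ## homozygote frequency 0.6^2 = 0.36 per locus puts P(score >= 3) ~ 0.25
    risk_allele_freqs <- stats::setNames(rep(0.6, 5), udef$loci$rsid)
  }
  if (is.null(eqtl_allele_freqs)) {
    eqtl_allele_freqs <- stats::setNames(rep(0.5, 5), wdef$loci$rsid)
  }
  sc <- list(
    n_subjects = as.integer(n_subjects), prop_male = prop_male,
    prop_ancestry = prop_ancestry, prop_urine_pm = prop_urine_pm,
    bpa_logmean = bpa_logmean, bpa_logsd = bpa_logsd, lod = lod,
    frac_bpa_missing = frac_bpa_missing, frac_asp_missing = frac_asp_missing,
    interaction_or = interaction_or, baseline_or = baseline_or,
    male_or = male_or, outcome_prevalence = outcome_prevalence,
    asp_high_prev = asp_high_prev, asp_asd_or = asp_asd_or,
    risk_allele_freqs = risk_allele_freqs,
    eqtl_allele_freqs = eqtl_allele_freqs,
    meth_slope_per_log2 = meth_slope_per_log2,
    noise_sd_meth = noise_sd_meth,
    mediation_a = mediation_a, mediation_b = mediation_b,
    mediation_direct = mediation_direct,
    mediation_noise_sd = mediation_noise_sd,
    seed = as.integer(seed)
  )
  stopifnot(
    sc$n_subjects >= 0,
    sc$prop_male >= 0, sc$prop_male <= 1,
    sc$lod > 0, sc$interaction_or > 0, sc$baseline_or > 0, sc$male_or > 0,
    sc$outcome_prevalence >= 0, sc$outcome_prevalence <= 1,
    sc$noise_sd_meth > 0, sc$mediation_noise_sd > 0,
    all(unlist(sc[c("frac_bpa_missing", "frac_asp_missing")]) >= 0),
    all(unlist(sc[c("frac_bpa_missing", "frac_asp_missing")]) < 1)
  )
  structure(sc, class = "sim_scenario")
}

## Solve the logistic intercept so that mean(plogis(b0 + offset)) = target.
calibrate_intercept <- function(offset, target) {
  if (target <= 0) return(-Inf)
  f <- function(b0) mean(stats::plogis(b0 + offset)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

hwe_genotypes <- function(n, allele, alt, freq) {
  ## genotype strings under Hardy-Weinberg for a biallelic locus
  g <- stats::rbinom(n, 2, freq)  # copies of `allele`
  c(paste0(alt, alt), paste0(allele, alt), paste0(allele, allele))[g + 1]
}

## alternate (non-risk / non-promoting) allele used opposite each target
other_allele <- function(a) c(A = "G", C = "T", G = "A", T = "C")[a]

#' Generate a synthetic cohort
#'
#' Draws a full cohort table with the structure described in
#' [sim_scenario()]: lognormal exposure left-censored at the LOD, five-SNP
#' genotypes at stated frequencies, a binary ASD outcome from a logistic
#' model whose exposure coefficient is `log(interaction_or)` in the (male,
#' low-aromatase-score) stratum and `log(baseline_or)` elsewhere, ASP
#' T-scores, promoter CpG beta values with the stated per-log2 slope, and
#' mediator / outcome methylation scores following
#' `mediator = a * exposed + noise`,
#' `outcome = b * mediator + direct * exposed + noise`.
#' Fully reproducible from the scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @return a validated cohort data frame (see [read_cohort()] for the
#'   column conventions; mediation variables are `med_aromatase` and
#'   `med_bdnf`). The latent uncensored exposure is kept in `bpa_true` —
#'   simulation ground truth that has no real-data counterpart; recovery
#'   tests regress against it, while analysis code must use `bpa_raw` with
#'   the LOD policy.
#' @export
generate_cohort <- function(scenario = sim_scenario()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  n <- sc$n_subjects
  windows <- default_methyl_windows()
  all_cpgs <- unique(unlist(lapply(windows[c("pif15", "pii", "control")],
                                   function(w) w$cpg_ids)))
  promoter_cpgs <- unique(c(windows$pif15$cpg_ids, windows$pii$cpg_ids))

  if (n == 0) {
    return(empty_cohort(sc, all_cpgs))
  }
  if (n * sc$outcome_prevalence < 1) {
    warning("generate_cohort: expected case count below 1 at this n and prevalence")
  }

  with_seed(sc$seed, {
    subject_id <- sprintf("S%05d", seq_len(n))
    sex <- ifelse(stats::runif(n) < sc$prop_male, "male", "female")
    ancestry_caucasian4 <- stats::runif(n) < sc$prop_ancestry
    urine_time_pm <- stats::runif(n) < sc$prop_urine_pm

    ## exposure: lognormal, left-censored at the LOD, some measures missing
    bpa_true <- stats::rlnorm(n, sc$bpa_logmean, sc$bpa_logsd)
    below <- bpa_true < sc$lod
    bpa_raw <- ifelse(below, sc$lod, bpa_true)
    specific_gravity <- pmax(1.001, stats::rnorm(n, 1.015, 0.005))
    bpa_missing <- stats::runif(n) < sc$frac_bpa_missing
    bpa_raw[bpa_missing] <- NA_real_
    below_lod <- ifelse(bpa_missing, NA, below)
    bpa_sg <- sg_correct(bpa_raw, specific_gravity,
                         stats::median(specific_gravity))

    ## genotypes: unweighted-score SNPs (risk genotype = homozygous risk
    ## allele) and eQTLs for the weighted score; loci independent (the score
    ## is additive, LD is irrelevant to its arithmetic)
    udef <- unweighted_score_definition()
    wdef <- weighted_score_definition()
    geno <- list()
    for (i in seq_len(nrow(udef$loci))) {
      rsid <- udef$loci$rsid[i]
      risk <- substr(udef$loci$target[i], 1, 1)
      geno[[paste0("geno_", rsid)]] <-
        hwe_genotypes(n, risk, other_allele(risk), sc$risk_allele_freqs[[rsid]])
    }
    for (i in seq_len(nrow(wdef$loci))) {
      rsid <- wdef$loci$rsid[i]
      promo <- wdef$loci$target[i]
      geno[[paste0("geno_", rsid)]] <-
        hwe_genotypes(n, promo, other_allele(promo), sc$eqtl_allele_freqs[[rsid]])
    }

    ## the true stratum: male with low unweighted aromatase score
    uscore <- Reduce(`+`, lapply(seq_len(nrow(udef$loci)), function(i) {
      as.integer(geno[[paste0("geno_", udef$loci$rsid[i])]] ==
                   udef$loci$target[i])
    }))
    low_arom <- uscore >= 3
    male <- sex == "male"

    ## binary outcome: logistic with stratum-specific exposure coefficient
    thr75 <- stats::quantile(bpa_true, 0.75, type = 7, names = FALSE)
    high_bpa <- bpa_true > thr75
    beta_exp <- ifelse(male & low_arom, log(sc$interaction_or),
                       log(sc$baseline_or))
    off_dx <- log(sc$male_or) * male + beta_exp * high_bpa
    b0 <- calibrate_intercept(off_dx, sc$outcome_prevalence)
    asd_dx9 <- stats::runif(n) < stats::plogis(b0 + off_dx)

    ## ASP T-score: high/low via a logistic sharing the exposure structure,
    ## coupled to diagnosis so the score is predictive of later ASD
    off_asp <- beta_exp * high_bpa + log(sc$asp_asd_or) * asd_dx9
    a0 <- calibrate_intercept(off_asp, sc$asp_high_prev)
    asp_high <- stats::runif(n) < stats::plogis(a0 + off_asp)
    asp_tscore <- ifelse(asp_high,
                         51L + stats::rpois(n, 3),
                         50L - pmin(stats::rpois(n, 1), 22L))
    asp_tscore <- as.integer(pmax(asp_tscore, 28L))
    asp_tscore[stats::runif(n) < sc$frac_asp_missing] <- NA_integer_

    ## year-9 screen timing
    dx_screen_age <- stats::rnorm(n, 9.05, 0.74)
    birth <- as.Date("2010-06-15") + floor(stats::runif(n, 0, 1095))
    dx_screen_date <- birth + round(dx_screen_age * 365.25)

    ## promoter methylation: per-log2 slope on the beta scale; control
    ## window CpGs carry no exposure signal
    slope_beta <- sc$meth_slope_per_log2 / 100
    l2b <- log2(bpa_true)
    base_beta <- stats::setNames(rep(0.55, length(all_cpgs)), all_cpgs)
    base_beta[windows$pif15$cpg_ids] <- 0.10
    base_beta[windows$pii$cpg_ids] <- 0.12
    meth <- sapply(all_cpgs, function(cpg) {
      mu <- base_beta[[cpg]] +
        if (cpg %in% promoter_cpgs) slope_beta * l2b else 0
      pmin(pmax(mu + stats::rnorm(n, 0, sc$noise_sd_meth), 0), 1)
    })
    colnames(meth) <- all_cpgs

    ## mediation chain on the high-exposure category (> 4 ug/L)
    exposed4 <- as.numeric(bpa_true > 4)
    med_aromatase <- sc$mediation_a * exposed4 +
      stats::rnorm(n, 0, sc$mediation_noise_sd)
    med_bdnf <- sc$mediation_b * med_aromatase +
      sc$mediation_direct * exposed4 +
      stats::rnorm(n, 0, sc$mediation_noise_sd)

    ## cord-blood cell proportions (6 types, sum to 1)
    shapes <- c(cd4t = 4, cd8t = 2.5, bcell = 1.5, nk = 1.2, mono = 1.5,
                gran = 9)
    raw <- sapply(names(shapes), function(ct) stats::rgamma(n, shapes[[ct]], 1))
    cells <- raw / rowSums(raw)
    colnames(cells) <- paste0("cell_", names(shapes))

    gestational_age <- stats::rnorm(n, 39.4, 1.5)

    cohort <- data.frame(
      subject_id = subject_id, sex = sex,
      ancestry_caucasian4 = ancestry_caucasian4,
      urine_time_pm = urine_time_pm,
      bpa_raw = bpa_raw, bpa_sg = bpa_sg, bpa_below_lod = below_lod,
      bpa_true = bpa_true,
      specific_gravity = specific_gravity,
      as.data.frame(geno, stringsAsFactors = FALSE),
      asp_tscore = asp_tscore, asd_dx9 = asd_dx9,
      dx_screen_date = dx_screen_date, dx_screen_age = dx_screen_age,
      as.data.frame(meth), as.data.frame(cells),
      med_aromatase = med_aromatase, med_bdnf = med_bdnf,
      gestational_age = gestational_age,
      stringsAsFactors = FALSE
    )
    validate_cohort(cohort)
    aw_log("generate_cohort: n=%d, cases=%d, below LOD=%.1f%%",
           n, sum(asd_dx9), 100 * mean(below))
    cohort
  })
}

#' Generate a null cohort
#'
#' As [generate_cohort()] but with every exposure-outcome,
#' exposure-methylation and mediation coefficient set to its null value;
#' intended for type-I-error and coverage suites.
#'
#' @param scenario a [sim_scenario()].
#' @return a cohort data frame.
#' @export
generate_null_cohort <- function(scenario = sim_scenario()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  null_sc <- scenario
  null_sc$interaction_or <- 1
  null_sc$baseline_or <- 1
  null_sc$meth_slope_per_log2 <- 0
  null_sc$mediation_a <- 0
  null_sc$mediation_b <- 0
  null_sc$mediation_direct <- 0
  generate_cohort(null_sc)
}

empty_cohort <- function(sc, all_cpgs) {
  udef <- unweighted_score_definition()
  wdef <- weighted_score_definition()
  cols <- c("subject_id", "sex", "ancestry_caucasian4", "urine_time_pm",
            "bpa_raw", "bpa_sg", "bpa_below_lod", "bpa_true",
            "specific_gravity",
            paste0("geno_", c(udef$loci$rsid, wdef$loci$rsid)),
            "asp_tscore", "asd_dx9", "dx_screen_date", "dx_screen_age",
            all_cpgs,
            paste0("cell_", c("cd4t", "cd8t", "bcell", "nk", "mono", "gran")),
            "med_aromatase", "med_bdnf", "gestational_age")
  out <- as.data.frame(stats::setNames(
    replicate(length(cols), logical(0), simplify = FALSE), cols))
  out$subject_id <- character(0)
  out$dx_screen_date <- as.Date(character(0))
  out
}
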