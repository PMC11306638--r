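pipeline_stage_order <- c("simulate", "exposure", "score", "match", "clr",
                          "risk", "methylation", "mediation", "concordance")

## Flatten an aroma_clr (or skip record) for JSON serialization.
clr_to_list <- function(fit) {
  if (!inherits(fit, "aroma_clr")) return(fit)
  list(beta = as.list(fit$beta), se = as.list(fit$se),
       or = fit$or, ci_low = fit$ci[1], ci_high = fit$ci[2],
       loglik = fit$loglik, n_sets = fit$n_sets_informative,
       n_sets_dropped = fit$n_sets_dropped,
       converged = fit$converged, separation = fit$separation_flag)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order on a synthetic cohort:
#' `simulate` -> `exposure` -> `score` -> `match` -> `clr` -> `risk` ->
#' `methylation` -> `mediation` -> `concordance`. Each stage writes a JSON
#' (or CSV/TSV) artifact into `out_dir` and is recorded in the returned
#' manifest with its input/output paths and record counts. One root seed
#' drives everything; each stage derives its own RNG stream keyed by stage
#' name, so a second run with the same configuration and seed reproduces
#' all numeric outputs exactly.
#'
#' @param config an [aroma_config()]; `config$seed` is the root seed.
#' @param scenario a [sim_scenario()] for the simulate stage; its seed is
#'   overridden by the stage stream.
#' @param stages character vector, a prefix of the canonical stage order.
#' @param out_dir output directory (created if needed).
#' @param direction_table path to a pathway direction TSV for the
#'   concordance stage; defaults to the bundled synthetic example.
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json` as well.
#' @export
run_pipeline <- function(config = aroma_config(),
                         scenario = sim_scenario(),
                         stages = pipeline_stage_order,
                         out_dir = tempfile("aromawise_run_"),
                         direction_table = system.file(
                           "extdata", "pathway_directions_synthetic.tsv",
                           package = "aromawise")) {
  bad <- setdiff(stages, pipeline_stage_order)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  k <- max(match(stages, pipeline_stage_order))
  if (!setequal(stages, pipeline_stage_order[seq_len(k)])) {
    stop("run_pipeline: stages must form a prefix of the stage order (",
         paste(pipeline_stage_order, collapse = " -> "), ")")
  }
  stages <- pipeline_stage_order[seq_len(k)]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    version = as.character(utils::packageVersion("aromawise")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  record <- function(stage, inputs, outputs, n_records) {
    manifest$stages[[stage]] <<- list(inputs = inputs, outputs = outputs,
                                      n_records = n_records)
  }
  wr <- function(obj, file) {
    path <- file.path(out_dir, file)
    write_results(obj, path, seed = config$seed, config = config)
    path
  }

  cohort <- NULL
  env <- new.env(parent = emptyenv())
  for (stage in stages) {
    switch(stage,
      simulate = {
        scenario$seed <- stage_seed(config$seed, "simulate")
        cohort <- generate_cohort(scenario)
        path <- file.path(out_dir, "cohort.csv")
        write_cohort(cohort, path)
        record("simulate", character(0), path, nrow(cohort))
      },
      exposure = {
        dich <- dichotomize_exposure(cohort$bpa_raw, config$exposure_quantile)
        env$high_bpa <- dich$high
        env$bpa_imp <- impute_below_lod(cohort$bpa_raw, cohort$bpa_below_lod,
                                        config$lod_value, config$lod_policy)
        med_conc <- stats::median(cohort$bpa_raw, na.rm = TRUE)
        intake <- urinary_to_intake(med_conc, config$urine_output_l_per_day,
                                    config$fractional_excretion,
                                    config$bodyweight_kg)
        tdi <- apply_safety_factors(intake$intake, config$safety_factors)
        out <- list(threshold = dich$threshold,
                    n_high = sum(dich$high, na.rm = TRUE),
                    n_measured = sum(!is.na(cohort$bpa_raw)),
                    frac_below_lod = mean(cohort$bpa_below_lod, na.rm = TRUE),
                    median_conc = med_conc,
                    intake_ng_kg_day = intake$intake,
                    intake_presented = intake$presented,
                    tdi_ng_kg_day = tdi)
        record("exposure", manifest$stages$simulate$outputs,
               wr(out, "exposure.json"), out$n_measured)
      },
      score = {
        env$uscores <- aromatase_score(cohort, unweighted_score_definition())
        env$wscores <- aromatase_score(cohort, weighted_score_definition())
        out <- list(
          unweighted = list(n_low = sum(env$uscores$low_aromatase, na.rm = TRUE),
                            n_scoreable = sum(env$uscores$scoreable)),
          weighted = list(n_low = sum(env$wscores$low_aromatase, na.rm = TRUE),
                          n_scoreable = sum(env$wscores$scoreable))
        )
        record("score", manifest$stages$simulate$outputs,
               wr(out, "score.json"), nrow(env$uscores))
      },
      match = {
        sets <- matched_design(cohort,
                               stratum_vars = c("sex", "ancestry_caucasian4",
                                                "urine_time_pm"),
                               outcome = "asd_dx9", m = config$match_m,
                               seed = stage_seed(config$seed, "match"))
        env$sets <- sets
        path <- file.path(out_dir, "matched_sets.tsv")
        utils::write.table(sets, path, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        record("match", manifest$stages$simulate$outputs, path,
               length(unique(sets$set_id)))
      },
      clr = {
        env$strat <- stratified_interaction_analysis(cohort, config)
        out <- lapply(env$strat, clr_to_list)
        record("clr", manifest$stages$simulate$outputs,
               wr(out, "clr_stratified.json"), length(out))
      },
      risk = {
        fit_ml <- env$strat[["male:low"]]
        risk <- list()
        if (inherits(fit_ml, "aroma_clr")) {
          expo <- stats::setNames(env$high_bpa, cohort$subject_id)
          paf <- paf_with_ci(fit_ml$design, expo,
                             n_boot = config$bootstrap_reps,
                             seed = stage_seed(config$seed, "paf"))
          risk$paf_male_low <- unclass(paf)
        }
        ok <- !is.na(cohort$asp_tscore) & !is.na(cohort$asd_dx9)
        roc <- roc_auc(cohort$asp_tscore[ok], cohort$asd_dx9[ok])
        lr <- likelihood_ratios(cohort$asp_tscore[ok] > 50, cohort$asd_dx9[ok])
        risk$asp_roc <- roc
        risk$asp_lr <- lr
        record("risk", manifest$stages$clr$outputs,
               wr(risk, "risk.json"), sum(ok))
      },
      methylation = {
        windows <- default_methyl_windows()
        covars <- cbind(
          data.frame(male = as.numeric(cohort$sex == "male"),
                     gestational_age = cohort$gestational_age,
                     ancestry = as.numeric(cohort$ancestry_caucasian4)),
          cohort[cell_cols(cohort)][-1]  # drop one proportion: they sum to 1
        )
        out <- lapply(windows, function(w) {
          avg <- window_mean(cohort[cpg_cols(cohort)], w)
          unclass(window_association(avg, env$bpa_imp, covars,
                                     window_name = w$name))
        })
        record("methylation", manifest$stages$simulate$outputs,
               wr(out, "methylation.json"), nrow(cohort))
      },
      mediation = {
        ok <- !is.na(cohort$bpa_raw)
        cat4 <- categorize_for_epigenetics(cohort$bpa_raw[ok],
                                           config$contrast_mode,
                                           config$high_bpa_cutoff_epigenetics)
        keep <- cat4 != "excluded"
        covars <- data.frame(male = as.numeric(cohort$sex == "male")[ok][keep],
                             gestational_age = cohort$gestational_age[ok][keep])
        med <- mediate(cat4[keep] == "exposed",
                       cohort$med_aromatase[ok][keep],
                       cohort$med_bdnf[ok][keep],
                       covars = covars,
                       n_boot = config$bootstrap_reps,
                       seed = stage_seed(config$seed, "mediation"))
        record("mediation", manifest$stages$simulate$outputs,
               wr(unclass(med), "mediation.json"), med$n)
      },
      concordance = {
        tab <- read_direction_table(direction_table)
        out <- list(
          opposition = opposite_direction_binomial(tab),
          axon_dendrite_a = term_direction_fisher(tab, "axon|dendrit", "a"),
          axon_dendrite_b = term_direction_fisher(tab, "axon|dendrit", "b")
        )
        out$axon_dendrite_a$contingency <-
          as.data.frame(out$axon_dendrite_a$contingency)
        out$axon_dendrite_b$contingency <-
          as.data.frame(out$axon_dendrite_b$contingency)
        record("concordance", direction_table,
               wr(out, "concordance.json"), nrow(tab))
      }
    )
    aw_log("pipeline: stage '%s' complete", stage)
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
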