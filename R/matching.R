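#' Partition subjects into matching strata
#'
#' Splits a cohort on the supplied (categorical) stratum variables — e.g.
#' ancestry and time of urine collection, with sex added for full-sample
#' analyses. Subjects with a missing stratum variable are excluded with a
#' log entry; per-stratum counts are logged.
#'
#' @param cohort cohort data frame.
#' @param vars character vector of stratum column names.
#' @return named list mapping stratum label -> character vector of
#'   subject ids.
#' @export
stratify <- function(cohort, vars) {
  miss <- setdiff(vars, names(cohort))
  if (length(miss)) stop("stratify: unknown stratum variables: ",
                         paste(miss, collapse = ", "))
  ok <- stats::complete.cases(cohort[vars])
  if (any(!ok)) {
    aw_log("stratify: excluded %d subjects with missing stratum variables",
           sum(!ok))
  }
  sub <- cohort[ok, , drop = FALSE]
  key <- do.call(paste, c(lapply(vars, function(v) {
    paste0(v, "=", sub[[v]])
  }), sep = "|"))
  out <- split(sub$subject_id, key)
  aw_log("stratify: %d strata (%s)", length(out),
         paste(sprintf("%s: %d", names(out), lengths(out)), collapse = "; "))
  out
}

## Order candidate controls for one case: |date difference| in days, ties by
## |age difference| in years, then subject id for stability.
nearest_control <- function(case_date, case_age, ctrl) {
  dd <- abs(as.numeric(ctrl$date - case_date))
  da <- abs(ctrl$age - case_age)
  ctrl$subject_id[order(dd, da, ctrl$subject_id)][1]
}

#' Build matched case-control sets by iterative nearest-neighbour rounds
#'
#' Implements round-robin greedy matching within a stratum: in each of `m`
#' rounds the cases are taken in a fresh seeded random order, and each case
#' in turn claims its nearest not-yet-used control (smallest absolute
#' difference in screen date, ties broken by age difference, then id).
#' Controls are never reused across the design; cases that exhaust the
#' control supply keep fewer controls, with a log entry.
#'
#' @param cases data frame with columns `subject_id`, `date` (`Date`) and
#'   `age` (decimal years), one row per case in the stratum.
#' @param controls data frame of the same shape for candidate controls.
#' @param m target controls per case.
#' @param seed integer seed; each round draws its case order from a
#'   dedicated stream derived from it.
#' @param stratum optional label stored on the output.
#' @return data frame of matched sets: `set_id`, `subject_id`, `role`
#'   (`"case"`/`"control"`), `stratum`, `m_target`. One set per case, the
#'   case row first, controls in the order claimed.
#' @export
build_matched_sets <- function(cases, controls, m = 8L, seed = 1L,
                               stratum = NA_character_) {
  stopifnot(all(c("subject_id", "date", "age") %in% names(cases)),
            all(c("subject_id", "date", "age") %in% names(controls)),
            m >= 1)
  if (nrow(controls) == 0 && nrow(cases) > 0) {
    warning("build_matched_sets: no controls in stratum; sets will be empty")
  }
  if (length(intersect(cases$subject_id, controls$subject_id))) {
    stop("build_matched_sets: case and control id sets overlap")
  }
  assigned <- stats::setNames(
    lapply(cases$subject_id, function(...) character(0)), cases$subject_id)
  used <- character(0)
  for (round in seq_len(m)) {
    order_ids <- with_seed(stage_seed(seed, sprintf("match-round-%03d", round)),
                           sample(cases$subject_id))
    for (cid in order_ids) {
      avail <- controls[!controls$subject_id %in% used, , drop = FALSE]
      if (nrow(avail) == 0) next
      crow <- cases[cases$subject_id == cid, ]
      pick <- nearest_control(crow$date, crow$age, avail)
      assigned[[cid]] <- c(assigned[[cid]], pick)
      used <- c(used, pick)
    }
  }
  short <- names(assigned)[lengths(assigned) < m]
  if (length(short)) {
    aw_log("build_matched_sets: %d of %d cases matched to fewer than %d controls (control supply exhausted)",
           length(short), nrow(cases), m)
  }
  rows <- lapply(seq_along(assigned), function(i) {
    cid <- names(assigned)[i]
    ids <- c(cid, assigned[[i]])
    data.frame(
      set_id = sprintf("set_%s", cid),
      subject_id = ids,
      role = c("case", rep("control", length(ids) - 1L)),
      stratum = stratum,
      m_target = as.integer(m),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Structural checks on a matched design: one case per set, no control
## reuse, set sizes within target.
assert_matched_design <- function(sets) {
  stopifnot(is.data.frame(sets),
            all(c("set_id", "subject_id", "role") %in% names(sets)))
  cases_per_set <- tapply(sets$role == "case", sets$set_id, sum)
  if (any(cases_per_set != 1)) stop("matched design: a set without exactly one case")
  ctrl <- sets$subject_id[sets$role == "control"]
  if (anyDuplicated(ctrl)) stop("matched design: control reused across sets")
  sizes <- table(sets$set_id) - 1L
  if (any(sizes > sets$m_target[1])) stop("matched design: set larger than target")
  invisible(sets)
}

#' Build a full matched design across strata
#'
#' Convenience wrapper: stratifies eligible subjects, then runs
#' [build_matched_sets()] within each stratum and binds the results.
#'
#' @param cohort cohort data frame; needs `asd_dx9` (or the column named in
#'   `outcome`), `dx_screen_date`, `dx_screen_age` and the stratum columns.
#' @param stratum_vars stratum column names.
#' @param outcome logical outcome column defining cases.
#' @param m controls per case.
#' @param seed integer seed.
#' @return matched-set data frame as from [build_matched_sets()].
#' @export
matched_design <- function(cohort, stratum_vars = c("ancestry_caucasian4",
                                                    "urine_time_pm"),
                           outcome = "asd_dx9", m = 8L, seed = 1L) {
  stopifnot(outcome %in% names(cohort))
  eligible <- cohort[!is.na(cohort[[outcome]]) &
                       stats::complete.cases(cohort[stratum_vars]), ,
                     drop = FALSE]
  strata <- stratify(eligible, stratum_vars)
  parts <- lapply(names(strata), function(lab) {
    ids <- strata[[lab]]
    sub <- eligible[eligible$subject_id %in% ids, , drop = FALSE]
    is_case <- sub[[outcome]]
    mk <- function(rows) data.frame(subject_id = rows$subject_id,
                                    date = rows$dx_screen_date,
                                    age = rows$dx_screen_age,
                                    stringsAsFactors = FALSE)
    if (!any(is_case)) return(NULL)
    build_matched_sets(mk(sub[is_case, ]), mk(sub[!is_case, ]), m = m,
                       seed = stage_seed(seed, paste0("stratum-", lab)),
                       stratum = lab)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    stop("matched_design: no cases in any stratum")
  }
  rownames(out) <- NULL
  assert_matched_design(out)
  aw_log("matched_design: %d sets, %d subjects",
         length(unique(out$set_id)), nrow(out))
  out
}
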