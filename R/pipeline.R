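# End-to-end orchestration: generate (or load) a cohort, trim and screen the
# recordings, score sleep/wake, extract the 40-feature battery, run the
# repeated SVM permutation-importance experiment and the group statistics,
# and write plain CSV/JSON artifacts so each stage stays independently
# re-runnable.

#' Extract the feature table for a generated cohort
#'
#' Trims every subject's recording to the protocol window, applies the
#' non-wear exclusion rule, scores sleep/wake, and builds the 40-feature
#' battery with the weekday-sleep-debt label. Subjects failing exclusion or
#' with unmeasurable required nights are dropped and counted.
#'
#' @param cohort result of [generate_cohort()].
#' @param max_nonwear_min non-wear exclusion threshold (minutes).
#' @param wsd_threshold rebound threshold (minutes) for the label.
#' @return A data frame (the cohort table) with one row per included
#'   subject: `subject`, the 40 features, `SRW`, `wsd_label`,
#'   `chronotype_class` and the questionnaire totals. Attribute `excluded`
#'   holds the dropped subject ids.
#' @export
cohort_features <- function(cohort, max_nonwear_min = 30,
                            wsd_threshold = WSD_THRESHOLD_MIN) {
  rows <- list()
  excluded <- integer(0)
  for (i in seq_along(cohort$subjects)) {
    bundle <- cohort$subjects[[i]]
    row <- tryCatch(
      {
        trimmed <- trim_to_protocol(bundle$series)
        if (!apply_exclusion(trimmed, max_nonwear_min)) {
          stop("excluded: non-wear run over ", max_nonwear_min, " min",
            call. = FALSE
          )
        }
        fv <- build_feature_vector(trimmed, wsd_threshold = wsd_threshold)
        cbind(
          data.frame(subject = i),
          as.data.frame(as.list(fv$features), check.names = FALSE),
          data.frame(
            SRW = fv$chronotype$SRW,
            wsd_label = fv$chronotype$wsd_label,
            chronotype_class = fv$chronotype$chronotype_class
          ),
          as.data.frame(as.list(bundle$questionnaires))
        )
      },
      error = function(e) e
    )
    if (inherits(row, "error")) {
      excluded <- c(excluded, i)
    } else {
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) stop("no subject survived screening", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Pooled actigraphy-vs-diary sleep-duration agreement
#'
#' Collects per-night (actigraphy SD, diary SD) pairs over all included
#' subjects and runs [bland_altman()] on them.
#'
#' @param cohort result of [generate_cohort()].
#' @param subjects subject ids to include (default: all).
#' @return An `agreement_report` ([bland_altman()]).
#' @export
diary_agreement <- function(cohort, subjects = seq_along(cohort$subjects)) {
  acti <- numeric(0)
  diary <- numeric(0)
  for (i in subjects) {
    bundle <- cohort$subjects[[i]]
    scored <- tryCatch(
      score_subject(trim_to_protocol(bundle$series)),
      error = function(e) NULL
    )
    if (is.null(scored)) next
    nights <- scored$nights
    matched <- merge(nights[, c("night", "SD")], bundle$diary[, c("night", "SD")],
      by = "night", suffixes = c("_acti", "_diary")
    )
    acti <- c(acti, matched$SD_acti)
    diary <- c(diary, matched$SD_diary)
  }
  bland_altman(acti, diary)
}

#' Run the full WSD analysis pipeline
#'
#' Orchestrates generate, screen, score, feature extraction, factor
#' identification and group statistics under one master seed, writing plain
#' CSV artifacts plus a JSON run log when `out_dir` is given. Reruns with
#' the same configuration produce identical outputs.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   `seed` (required master seed), `cohort` (arguments for
#'   [cohort_config()], `n` required), `experiment` (overrides for
#'   [experiment_config()]), `family_m_features` / `family_m_questionnaires`
#'   (Bonferroni family sizes, defaults 40 and 13), and optional `out_dir`.
#' @param out_dir output directory (overrides `config$out_dir`); `NULL`
#'   writes nothing.
#' @return A list with `features` (cohort table), `report`
#'   (importance report), `comparisons` (feature t-tests), `questionnaires`
#'   (questionnaire t-tests), `agreement` (Bland-Altman), `truth`, and
#'   `log` (seeds, counts, versions).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) {
    stop("pipeline config must name a master `seed`", call. = FALSE)
  }
  if (is.null(config$cohort$n)) {
    stop("pipeline config must give the cohort size `cohort$n`", call. = FALSE)
  }
  if (is.null(out_dir)) out_dir <- config$out_dir
  seed <- as.integer(config$seed)

  cc <- do.call(cohort_config, config$cohort)
  cohort <- generate_cohort(cc, seed)
  features <- cohort_features(cohort,
    wsd_threshold = cc$wsd_threshold
  )

  exp_args <- config$experiment
  if (is.null(exp_args)) exp_args <- list()
  if (is.null(exp_args$master_seed)) exp_args$master_seed <- seed
  ec <- do.call(experiment_config, exp_args)
  report <- run_experiment(features, ec)

  m_feat <- config$family_m_features
  if (is.null(m_feat)) m_feat <- 40L
  m_q <- config$family_m_questionnaires
  if (is.null(m_q)) m_q <- 13L
  q_vars <- intersect(
    c(
      "PSQI", "ESS", "SDS", "SRM", "MEQ",
      paste0("SF36_", c("PF", "RP", "BP", "GH", "VT", "SF", "RE", "MH"))
    ),
    names(features)
  )
  comparisons <- ttest_bonferroni(features, features$wsd_label,
    vars = intersect(feature_names(), names(features)), m = m_feat
  )
  questionnaires <- ttest_bonferroni(features, features$wsd_label,
    vars = q_vars, m = m_q
  )
  agreement <- diary_agreement(cohort, subjects = features$subject)

  log <- list(
    seed = seed,
    n_generated = cc$n,
    n_included = nrow(features),
    excluded_subjects = attr(features, "excluded"),
    n_wsd = sum(features$wsd_label),
    n_nonwsd = sum(!features$wsd_label),
    failed_repeats = report$n_failed,
    bonferroni_threshold_features = attr(comparisons, "threshold"),
    bonferroni_threshold_questionnaires = attr(questionnaires, "threshold"),
    r_version = as.character(getRversion())
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
      row.names = FALSE
    )
    utils::write.csv(report$importance, file.path(out_dir, "importance.csv"),
      row.names = FALSE
    )
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
      row.names = FALSE
    )
    utils::write.csv(questionnaires,
      file.path(out_dir, "questionnaires.csv"),
      row.names = FALSE
    )
    utils::write.csv(
      data.frame(
        mean = agreement$means, difference = agreement$differences
      ),
      file.path(out_dir, "bland_altman.csv"),
      row.names = FALSE
    )
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }

  list(
    features = features, report = report, comparisons = comparisons,
    questionnaires = questionnaires, agreement = agreement,
    truth = cohort$truth, log = log
  )
}
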