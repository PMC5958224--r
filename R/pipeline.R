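# End-to-end pipeline: simulate -> segment -> extract -> catalogue ->
# select -> classify, per measurement day, producing the classification
# report table.

#' Cross-validated accuracy of one simulated cohort
#'
#' Convenience wrapper for the per-day classification experiment: simulate a
#' labeled cohort under `preset`, extract the 105-parameter table, select
#' `k` features by Fisher-criterion SFS and evaluate stratified `folds`-fold
#' cross-validation with the linear maximum-margin classifier.
#'
#' @param preset Drought preset name (e.g. `"day3"`, `"day7"`).
#' @param seed Master seed (drives simulation and fold assignment).
#' @param n_control,n_drought Cohort sizes.
#' @param k Number of SFS features.
#' @param folds CV folds.
#' @param features Optional pre-specified feature names; skips SFS.
#' @return The [cv_classify()] report, with the selection attached as
#'   attribute `"selection"` when SFS ran.
#' @export
cohort_cv_accuracy <- function(preset, seed, n_control = 54,
                               n_drought = 54, k = 9, folds = 10,
                               features = NULL) {
  cohort <- simulate_cohort(n_control, n_drought, preset = preset,
                            seed = seed)
  tab <- cohort_feature_table(cohort)
  sel <- NULL
  if (is.null(features)) {
    sel <- sfs_select(tab, k = k)
    features <- sel
  }
  rep <- cv_classify(tab, features, folds = folds, seed = seed)
  if (!is.null(sel)) attr(rep, "selection") <- sel
  rep
}

#' Default pipeline configuration
#'
#' @param days Character vector of drought presets, one per report row.
#' @param genotypes Labels for replicate runs (each genotype gets an
#'   independent seed stream; the simulator itself is genotype-agnostic).
#' @param n_control,n_drought Cohort sizes per day.
#' @param k Number of features for [sfs_select()].
#' @param folds Cross-validation folds.
#' @param seed Master seed.
#' @param noise A [noise_model()].
#' @param spec A [rosette_spec()].
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(days = c("day1", "day3", "day5", "day7",
                                     "day8"),
                            genotypes = "WT", n_control = 54,
                            n_drought = 54, k = 9, folds = 10, seed = 1,
                            noise = noise_model(), spec = rosette_spec()) {
  list(days = days, genotypes = genotypes, n_control = n_control,
       n_drought = n_drought, k = k, folds = folds, seed = seed,
       noise = noise, spec = spec)
}

#' Run the full drought-classification pipeline
#'
#' For every genotype and day: simulates a labeled cohort, extracts the
#' 105-parameter feature table, selects `k` features by Fisher-criterion
#' SFS, and evaluates a stratified 10-fold cross-validated linear
#' maximum-margin classifier. Returns (and optionally writes) a report
#' shaped like a per-day classification table: control-class, drought-class
#' and overall accuracy in percent.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for CSV/JSON artifacts
#'   (`report.csv`, `selected_features.json`, per-day feature tables).
#' @return An object of class `pipeline_result`: `report` (data.frame),
#'   `selections` (named list of [sfs_select()] results), `tables` (named
#'   list of feature tables), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (config$n_control + config$n_drought <= 0) {
    stopf("stage simulate: empty cohort")
  }
  rows <- list()
  selections <- list()
  tables <- list()
  gi <- 0L
  for (gt in config$genotypes) {
    gi <- gi + 1L
    for (day in config$days) {
      key <- paste(gt, day, sep = ".")
      seed_i <- child_seed(config$seed, 131L * gi +
                             match(day, config$days))
      cohort <- tryCatch(
        simulate_cohort(config$n_control, config$n_drought, preset = day,
                        noise = config$noise, seed = seed_i,
                        spec = config$spec),
        error = function(e) stopf("stage simulate (%s): %s", key,
                                  conditionMessage(e)))
      tab <- cohort_feature_table(cohort, day = day, genotype = gt)
      sel <- tryCatch(sfs_select(tab, k = config$k),
                      error = function(e)
                        stopf("stage select (%s): %s", key,
                              conditionMessage(e)))
      rep_i <- tryCatch(
        cv_classify(tab, sel, folds = config$folds, seed = seed_i),
        error = function(e) stopf("stage classify (%s): %s", key,
                                  conditionMessage(e)))
      rows[[key]] <- data.frame(
        day = day, genotype = gt,
        control_pct = rep_i$control, drought_pct = rep_i$drought,
        overall_pct = rep_i$overall, seed = seed_i,
        stringsAsFactors = FALSE)
      selections[[key]] <- sel
      tables[[key]] <- tab
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    writeLines(jsonlite::toJSON(lapply(selections, `[[`, "selected")),
               file.path(out_dir, "selected_features.json"))
    for (key in names(tables)) {
      write_feature_table(tables[[key]],
                          file.path(out_dir, paste0("features_", key,
                                                    ".csv")))
    }
  }
  structure(list(report = report, selections = selections,
                 tables = tables, config = config),
            class = "pipeline_result")
}
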