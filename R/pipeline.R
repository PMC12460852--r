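#' Summarise cohort demographics
#'
#' Counts and arithmetic means over a demographic table after removing
#' records marked as excluded.  The age mean is reported to one decimal.
#'
#' @param records data.frame with columns `sex` (`"M"`/`"F"`), `age`
#'   (years), optionally `excluded` (reason string; empty/NA means
#'   included) and optionally `volume_pre_mm3` / `volume_post_mm3`.
#' @return list of class `cohort_summary`: `n_cases`, `n_male`,
#'   `n_female`, `mean_age`, mean volumes when present, and
#'   `exclusion_tally`.
#' @export
summarize_cohort <- function(records) {
  if (!all(c("sex", "age") %in% names(records)))
    stop("records must contain `sex` and `age` columns", call. = FALSE)
  if (anyNA(records$sex) || anyNA(records$age))
    stop("missing sex/age values", call. = FALSE)
  excl <- if ("excluded" %in% names(records)) {
    r <- as.character(records$excluded)
    !is.na(r) & nzchar(r)
  } else rep(FALSE, nrow(records))
  tally <- if (any(excl)) table(as.character(records$excluded)[excl]) else table(character(0))
  kept <- records[!excl, , drop = FALSE]
  sex <- toupper(substr(as.character(kept$sex), 1, 1))
  if (!all(sex %in% c("M", "F")))
    stop("sex must code male/female (M/F)", call. = FALSE)
  out <- list(n_cases = nrow(kept),
              n_male = sum(sex == "M"), n_female = sum(sex == "F"),
              mean_age = round(mean(kept$age), 1),
              exclusion_tally = tally)
  for (v in c("volume_pre_mm3", "volume_post_mm3"))
    if (v %in% names(kept)) out[[paste0("mean_", v)]] <- mean(kept[[v]])
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n=%d (%d male / %d female), mean age %.1f years",
              x$n_cases, x$n_male, x$n_female, x$mean_age))
  if (length(x$exclusion_tally))
    cat(sprintf("; %d excluded", sum(x$exclusion_tally)))
  cat("\n")
  invisible(x)
}

#' Demographics of the reference glioblastoma cohort
#'
#' Loads the packaged demographic table of the 32-case recurrent
#' glioblastoma study cohort (sex, age, Karnofsky performance status,
#' resection type, chemoradiotherapy).
#'
#' @return data.frame with one row per case.
#' @export
read_demographics <- function() {
  utils::read.csv(system.file("extdata", "gbm_cohort.csv",
                              package = "edemarec"),
                  stringsAsFactors = FALSE)
}

#' Analysis run configuration
#'
#' Collects every tunable of a cohort run: phantom spec, cohort size,
#' registration mode, feature list, model settings, tile settings and the
#' master seed.  All randomness in [run_cohort_analysis()] flows from
#' `seed` through fixed named substreams (cohort generation, CV folds,
#' comparison classifiers).
#'
#' @param n_cases cohort size (default 32).
#' @param spec template [phantom_spec()].
#' @param registration `"supplied"` (use the known true transforms,
#'   default) or `"estimate"` (run [estimate_rigid()] per case).
#' @param features modelled feature names.
#' @param folds CV folds for the lasso screen and classifiers.
#' @param alpha_entry stepwise entry threshold.
#' @param tile_size,threshold,direction heatmap settings.
#' @param seed master seed.
#' @param output_dir optional directory for result files.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_cases = 32L, spec = phantom_spec(),
                       registration = c("supplied", "estimate"),
                       features = adc_feature_names(), folds = 10L,
                       alpha_entry = 0.05, tile_size = 2, threshold = 2.408,
                       direction = c("below_positive", "above_positive"),
                       seed = 1L, output_dir = NULL) {
  structure(list(n_cases = as.integer(n_cases), spec = spec,
                 registration = match.arg(registration),
                 features = features, folds = as.integer(folds),
                 alpha_entry = alpha_entry, tile_size = tile_size,
                 threshold = threshold, direction = match.arg(direction),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Serialize a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$spec <- NULL
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  write_phantom_spec(config$spec, sub("\\.json$", "_spec.json", path))
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- read_phantom_spec(sub("\\.json$", "_spec.json", path))
  do.call(run_config, c(cfg[setdiff(names(cfg), "spec")], list(spec = spec)))
}

#' Run the full cohort analysis
#'
#' Generates (or accepts) a cohort of cases, brings each recurrent tumor
#' mask onto the pre-recurrence grid, partitions the edema, extracts the
#' histogram features of both sub-volumes, and runs the statistical
#' stage: paired Wilcoxon tests per feature, Spearman correlations of
#' each feature against sub-volume size, the lasso screen with
#' cross-validated lambda, forward stepwise logistic regression on the
#' surviving features, ROC analysis of the stepwise model, and the
#' SVM/random-forest comparison classifiers.  Cases failing validation
#' are skipped with a message; the run errors only if no case survives.
#' All outputs are deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @param cases optional precomputed list of cases (otherwise generated
#'   from `config$spec`).
#' @return list of class `cohort_analysis` with the feature table, test
#'   reports, `lasso`, `stepwise`, `roc`, `classifier_aucs` and the
#'   resolved `config`.
#' @export
run_cohort_analysis <- function(config = run_config(), cases = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed_cohort <- config$seed
  seed_cv <- config$seed + 1L
  seed_clf <- config$seed + 2L

  if (is.null(cases))
    cases <- generate_cohort(config$n_cases, config$spec, seed_cohort)

  transforms <- lapply(cases, function(cs) {
    if (config$registration == "supplied") invert_rigid(cs$misalignment)
    else estimate_rigid(cs$adc_pre, cs$adc_post)
  })

  table <- cohort_feature_table(cases, transforms)

  feat <- config$features
  wide <- stats::reshape(table[, c("case_id", "label", feat)],
                         direction = "wide", idvar = "case_id",
                         timevar = "label", sep = ".")
  wilcoxon <- lapply(stats::setNames(feat, feat), function(f)
    wilcoxon_paired(wide[[paste0(f, ".rec")]], wide[[paste0(f, ".no_rec")]]))
  spearman <- lapply(stats::setNames(feat, feat), function(f)
    spearman_test(table[[f]], table$volume_mm3))

  lasso <- lasso_logistic_path(table, feat, folds = config$folds,
                               seed = seed_cv)
  stepwise <- forward_stepwise_logistic(table, lasso$selected_features,
                                        alpha_entry = config$alpha_entry)
  roc <- if (!stepwise$intercept_only)
    roc_analysis(stepwise_scores(stepwise, table), table$label,
                 direction = "auto")
  else NULL
  clf <- comparison_classifiers(table, feat, folds = config$folds,
                                seed = seed_clf)

  out <- structure(list(feature_table = table, wilcoxon = wilcoxon,
                        spearman = spearman, lasso = lasso,
                        stepwise = stepwise, roc = roc,
                        classifier_aucs = c(svm = clf$svm$auc,
                                            random_forest = clf$random_forest$auc),
                        config = config, n_cases_used = nrow(table) / 2),
                   class = "cohort_analysis")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(table, file.path(config$output_dir, "features.csv"))
    write_model_report(lasso, stepwise,
                       file.path(config$output_dir, "model_report.csv"))
    write_run_config(config, file.path(config$output_dir, "config.json"))
    sink(file.path(config$output_dir, "summary.txt"))
    print(out)
    sink()
  }
  out
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d cases (seed %d)\n", x$n_cases_used,
              x$config$seed))
  cat("  lasso selected:", paste(x$lasso$selected_features, collapse = ", "),
      "\n")
  if (!x$stepwise$intercept_only) {
    cat("  stepwise model:", paste(x$stepwise$included_features,
                                   collapse = ", "), "\n")
    cat(sprintf("  training AUC %.3f\n", x$roc$auc))
  } else cat("  stepwise model: intercept only\n")
  cat(sprintf("  comparison AUCs: SVM %.3f, random forest %.3f\n",
              x$classifier_aucs["svm"], x$classifier_aucs["random_forest"]))
  invisible(x)
}

#' Predict the recurrence-prone region of a single case
#'
#' Runs the location predictor on one case: selects the analysis slice
#' (largest tumor area with edema present, unless `slice_index` is
#' given), computes the tile ratio heatmap, optionally renders it and
#' writes the predicted mask, and scores the prediction when a
#' ground-truth recurrence mask is supplied.
#'
#' @param adc ADC `volume_image`.
#' @param edema edema [mask_volume()].
#' @param tumor optional tumor mask (needed when `slice_index` is `NULL`).
#' @param truth optional ground-truth recurrence mask for evaluation.
#' @param slice_index optional explicit slice.
#' @param tile_size,threshold,direction see [tile_ratio_map()].
#' @param output_dir optional directory receiving `heatmap.png`,
#'   `predicted_mask.nii.gz` and `prediction.json`.
#' @param case_id label used in the outputs.
#' @return list with `heatmap`, `slice_index`, `threshold` and (when
#'   truth is given) `evaluation`.
#' @export
run_case_prediction <- function(adc, edema, tumor = NULL, truth = NULL,
                                slice_index = NULL, tile_size = 2,
                                threshold = 2.408,
                                direction = c("below_positive",
                                              "above_positive"),
                                output_dir = NULL, case_id = "case") {
  direction <- match.arg(direction)
  if (is.null(slice_index)) {
    if (is.null(tumor))
      stop("either `tumor` or `slice_index` must be supplied", call. = FALSE)
    slice_index <- select_slice(tumor, edema)
  }
  hm <- tile_ratio_map(adc, edema, slice_index, tile_size = tile_size,
                       threshold = threshold, direction = direction)
  out <- list(heatmap = hm, slice_index = slice_index,
              threshold = threshold, tile_size = tile_size,
              case_id = case_id)
  if (!is.null(truth))
    out$evaluation <- evaluate_prediction(hm, truth, edema)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    render_heatmap(hm, adc, file.path(output_dir,
                                      paste0(case_id, "_heatmap.png")))
    heatmap_mask(hm, file.path(output_dir,
                               paste0(case_id, "_predicted_mask.nii.gz")))
    meta <- list(case_id = case_id, slice_index = slice_index,
                 tile_size = tile_size, threshold = threshold,
                 direction = direction,
                 evaluation = out$evaluation)
    jsonlite::write_json(meta, file.path(output_dir,
                                         paste0(case_id, "_prediction.json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
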