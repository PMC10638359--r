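#' Default candidate bias models
#'
#' The three bias-model forms fitted by OLS, plus WLS variants weighting by
#' modality or scanner so each group contributes equally to the fit.
#'
#' @return List of [bias_model_spec()] objects.
#' @export
default_bias_candidates <- function() {
  list(bias_model_spec("marginal", "OLS"),
       bias_model_spec("by_modality", "OLS"),
       bias_model_spec("by_scanner", "OLS"),
       bias_model_spec("marginal", "WLS", wls_grouping = "modality"),
       bias_model_spec("marginal", "WLS", wls_grouping = "scanner"),
       bias_model_spec("by_modality", "WLS", wls_grouping = "modality"),
       bias_model_spec("by_scanner", "WLS", wls_grouping = "scanner"))
}

#' Pipeline configuration
#'
#' Exactly one of `generator` (a [generator_config()]) or `input_csv` (a
#' cohort CSV with predictions) must be supplied.
#'
#' @param generator a [generator_config()], or `NULL` when reading a CSV.
#' @param input_csv path to a cohort CSV, or `NULL` when generating.
#' @param proportions split proportions (train / bias_estimation / test).
#' @param strata a [strata_spec()]; its forced-test rules determine which
#'   modalities and scanners are excluded from training and bias estimation.
#' @param candidates candidate bias models for cross-validated selection.
#' @param k_folds number of cross-validation folds.
#' @param bootstrap a [bootstrap_spec()] for the accuracy report.
#' @param reference_modality reference for the mixed-model contrasts.
#' @param exclude_modalities modalities excluded from the averaged slope
#'   contrast and the secondary reliability summaries (e.g. the failure
#'   modality).
#' @param seed master seed for splitting and evaluation stages.
#' @param out_dir optional directory for the report bundle.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_csv = NULL,
                            proportions = c(train = 0.71,
                                            bias_estimation = 0.12,
                                            test = 0.17),
                            strata = strata_spec(
                              forced_test_modalities = c("T1wFLAIR", "T2wGRE",
                                                         "IR"),
                              forced_test_scanners = c("Signa HDxt", "Skyra")),
                            candidates = default_bias_candidates(),
                            k_folds = 3,
                            bootstrap = bootstrap_spec(),
                            reference_modality = "MPRAGE",
                            exclude_modalities = "T2wGRE",
                            seed = 1L,
                            out_dir = NULL) {
  if (is.null(generator) == is.null(input_csv))
    stop("provide exactly one of 'generator' or 'input_csv'")
  structure(list(generator = generator, input_csv = input_csv,
                 proportions = proportions, strata = strata,
                 candidates = candidates, k_folds = k_folds,
                 bootstrap = bootstrap,
                 reference_modality = reference_modality,
                 exclude_modalities = exclude_modalities,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full brain-age bias-correction pipeline
#'
#' Generate (or load) a cohort with predictions; split participants into
#' train / bias-estimation / test; select a bias model by cross-validation on
#' the training set; fit the selected model on the bias-estimation set; apply
#' the age-independent inverse correction to the test set; and produce the
#' accuracy report (bootstrap metrics, brain-PAD slope tests, mixed-model
#' within-subject contrasts) and the reliability report (Cronbach's alpha,
#' within-subject mean absolute deviation). A manifest records seeds, sample
#' sizes and an audit that the three splits are pairwise disjoint.
#'
#' @param cfg a [pipeline_config()].
#' @return List with `cohort`, `split`, `folds`, `distribution_checks`,
#'   `selection`, `final_fit`, `test_records` (with `corrected` and
#'   `corrected_pad`), `accuracy`, `slope_test`, `mixed_model`,
#'   `reliability` and `manifest`. When `cfg$out_dir` is set, the bundle is
#'   also written to disk as CSV/JSON artifacts.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  cohort <- stage("cohort", {
    if (!is.null(cfg$input_csv)) {
      read_cohort(cfg$input_csv)
    } else {
      gen <- cfg$generator
      co <- build_cohort(gen)
      co <- if (gen$null_mode) generate_null_predictions(co, gen) else
        generate_predictions(co, gen)
      if (gen$slice_count > 0 && !gen$null_mode)
        co <- aggregate_cohort_slices(co)
      co
    }
  })

  split <- stage("split", stratified_split(cohort, cfg$proportions,
                                           cfg$strata,
                                           derive_seed(cfg$seed, "split")))
  checks <- stage("distribution-checks", check_distributions(cohort, split))

  train_ids <- split$participant_id[split$split == "train"]
  bias_ids <- split$participant_id[split$split == "bias_estimation"]
  test_ids <- split$participant_id[split$split == "test"]
  folds <- stage("cv-folds",
                 make_cv_folds(train_ids, cohort, cfg$k_folds,
                               strata = cfg$strata,
                               seed = derive_seed(cfg$seed, "cv")))

  train_recs <- cohort[cohort$participant_id %in% train_ids, ]
  bias_recs <- cohort[cohort$participant_id %in% bias_ids, ]
  test_recs <- cohort[cohort$participant_id %in% test_ids, ]

  selection <- stage("select-bias",
                     select_bias_model_cv(train_recs, cfg$candidates, folds))
  final_fit <- stage("fit-bias", fit_bias_model(bias_recs, selection$selected))

  test_recs$corrected <- stage("correct", correct_ages(test_recs, final_fit))
  test_recs$corrected_pad <- test_recs$corrected - test_recs$age

  corrected_view <- test_recs
  corrected_view$predicted_brain_age <- corrected_view$corrected
  accuracy <- stage("accuracy",
                    bootstrap_accuracy(corrected_view, cfg$bootstrap,
                                       pooled = TRUE))
  slope_test <- stage("slope-test", {
    avg_subset <- setdiff(unique(test_recs$modality), cfg$exclude_modalities)
    pad_slope_test(test_recs, test_recs$corrected_pad, avg_subset)
  })
  mixed <- stage("mixed-model",
                 mixed_abs_pad_model(test_recs, test_recs$corrected_pad,
                                     reference = cfg$reference_modality))
  reliability <- stage("reliability", {
    im <- build_item_matrix(test_recs, test_recs$corrected_pad)
    alpha_all <- cronbach_alpha(im)
    mad_all <- within_subject_mad(test_recs, test_recs$corrected_pad,
                                  boot = cfg$bootstrap)
    keep <- !(test_recs$modality %in% cfg$exclude_modalities)
    sub <- test_recs[keep, , drop = FALSE]
    alpha_sub <- tryCatch(
      cronbach_alpha(build_item_matrix(sub, sub$corrected_pad)),
      error = function(e) NULL)
    mad_sub <- within_subject_mad(test_recs, test_recs$corrected_pad,
                                  boot = cfg$bootstrap,
                                  exclude_modalities = cfg$exclude_modalities)
    list(item_matrix = im, alpha = alpha_all, mad = mad_all,
         alpha_excluding = alpha_sub, mad_excluding = mad_sub)
  })

  audit <- list(
    train_bias_disjoint = length(intersect(train_ids, bias_ids)) == 0,
    train_test_disjoint = length(intersect(train_ids, test_ids)) == 0,
    bias_test_disjoint = length(intersect(bias_ids, test_ids)) == 0,
    exhaustive = setequal(split$participant_id,
                          unique(cohort$participant_id)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("brainbias")),
    seed = cfg$seed,
    generator_seed = if (!is.null(cfg$generator)) cfg$generator$seed else NULL,
    input_csv = cfg$input_csv,
    n_participants = length(unique(cohort$participant_id)),
    n_scans = nrow(cohort),
    n_train = length(train_ids), n_bias = length(bias_ids),
    n_test = length(test_ids),
    selected_bias_model = bias_spec_label(selection$selected),
    final_coefficients = final_fit$coefficients,
    independence_audit = audit)

  result <- list(cohort = cohort, split = split, folds = folds,
                 distribution_checks = checks, selection = selection,
                 final_fit = final_fit, test_records = test_recs,
                 accuracy = accuracy, slope_test = slope_test,
                 mixed_model = mixed, reliability = reliability,
                 manifest = manifest)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    op <- function(f) file.path(cfg$out_dir, f)
    write_cohort(cohort, op("cohort.csv"))
    write_split_assignment(split, op("split.csv"), folds)
    write_bias_fit(final_fit, op("bias_fit.json"))
    utils::write.csv(accuracy, op("accuracy.csv"), row.names = FALSE)
    jsonlite::write_json(list(selection = selection$table,
                              slope_omnibus = slope_test$omnibus,
                              slope_average = slope_test$average[
                                c("estimate", "se", "p")],
                              contrasts = mixed$contrasts,
                              mae_hat = mixed$mae_hat),
                         op("accuracy.json"), auto_unbox = TRUE, digits = NA)
    write_reliability_report(reliability$alpha, reliability$mad,
                             op("reliability.json"))
    jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(result)
}
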