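# ---- sample-to-answer orchestration on synthetic cohorts ----

#' Run the full synthetic pipeline
#'
#' Orchestrates the complete study: simulate a cohort and its per-cartridge
#' feature vectors, apply the 3-sigma digital quality control, split patients
#' into training and held-out sets (all duplicates of a patient stay on one
#' side), train the eight-network cascade on the training side, predict the
#' held-out cartridges, and evaluate against the simulated ground truth. A
#' single-signal power-fit baseline is fit on the same training samples and
#' evaluated on the same held-out subset for comparison.
#'
#' @param config A [vfa_config()].
#' @param seed Integer master seed; all stages derive their seeds from it.
#' @param train_frac Fraction of patients assigned to training.
#' @param spec_overrides Passed to [train_cascade()].
#' @param log10_r Evaluate correlations on the log10 scale.
#' @return A list of class `vfa_pipeline`: `cohort`, `features` (with QC
#'   columns), `cascade`, `predictions`, `report` (per-biomarker tibble with
#'   cascade and baseline Pearson r), `test_ids`, `seed`.
#' @export
run_pipeline <- function(config = vfa_config(), seed = 1L, train_frac = 0.65,
                         spec_overrides = NULL, log10_r = FALSE) {
  cohort <- sample_cohort(config, seed = seed)
  features <- simulate_features(cohort, config, seed = seed + 1L)
  features <- qc_filter(features)
  passed <- dplyr::filter(features, .data$qc_status == "pass")

  patients <- unique(passed$patient_id)
  n_train <- max(1L, round(train_frac * length(patients)))
  train_pats <- withr::with_seed(seed + 2L, sample(patients, n_train))
  train <- dplyr::filter(passed, .data$patient_id %in% train_pats)
  test <- dplyr::filter(passed, !.data$patient_id %in% train_pats)

  cascade <- train_cascade(train, seed = seed + 3L,
                           spec_overrides = spec_overrides)
  predictions <- predict_cascade(cascade, test)
  report <- evaluate_cascade(predictions, test, log10_r = log10_r)

  # power-fit comparator per biomarker, fit on the same training samples
  baseline <- purrr::map_dfr(.biomarkers, function(bm) {
    sig <- train[[baseline_signal_col(bm)]]
    keep <- !train[[paste0("cens_", bm)]] & sig > 0
    mdl <- fit_power(tibble::tibble(conc = train[[paste0("conc_", bm)]][keep],
                                    signal = sig[keep]))
    pred_bm <- dplyr::filter(predictions, .data$biomarker == bm) |>
      dplyr::left_join(test, by = "sample_id")
    base_conc <- powerfit_baseline(pred_bm, mdl, bm, on_out_of_range = "na")
    q <- !is.na(pred_bm$conc) & !pred_bm[[paste0("cens_", bm)]] &
      !is.na(base_conc)
    r <- if (sum(q) >= 3) {
      correlation_report(base_conc[q], pred_bm[[paste0("conc_", bm)]][q],
                         log10 = log10_r)
    } else NA_real_
    tibble::tibble(biomarker = bm, r_baseline = r, baseline_model = list(mdl))
  })
  report <- dplyr::left_join(report, baseline, by = "biomarker")

  structure(
    list(cohort = cohort, features = features, cascade = cascade,
         predictions = predictions, report = report,
         test_ids = test$sample_id, seed = as.integer(seed)),
    class = "vfa_pipeline"
  )
}

#' @export
print.vfa_pipeline <- function(x, ...) {
  n_fail <- sum(x$features$qc_status == "fail")
  cat(sprintf("Synthetic study (seed %d): %d cartridges, %d failed QC, %d held out\n",
              x$seed, nrow(x$features), n_fail, length(x$test_ids)))
  print(dplyr::select(x$report, -"confusion", -"baseline_model"))
  invisible(x)
}

#' @export
glance.vfa_pipeline <- function(x, ...) {
  dplyr::select(x$report, -"confusion", -"baseline_model")
}
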