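# ---- metrics, the power-fit baseline, and cohort-level reports ----

#' Classification accuracy and confusion matrix
#'
#' @param predicted,truth Vectors of range labels, equal length.
#' @param labels Optional class set; labels outside it raise an error.
#' @return A list with `accuracy` (proportion correct), `n`, and `confusion`
#'   (a tibble, truth in rows); row sums equal the per-class truth counts.
#' @export
classification_report <- function(predicted, truth, labels = NULL) {
  if (length(predicted) != length(truth)) abort("inputs must have equal length")
  if (is.null(labels)) labels <- sort(unique(c(predicted, truth)))
  if (!all(c(predicted, truth) %in% labels)) {
    abort("label outside the declared class set")
  }
  pf <- factor(predicted, levels = labels)
  tf <- factor(truth, levels = labels)
  conf <- as.data.frame.matrix(table(truth = tf, predicted = pf))
  conf <- tibble::as_tibble(conf, rownames = "truth")
  list(accuracy = mean(predicted == truth), n = length(truth), confusion = conf)
}

#' Pearson correlation between predicted and true concentrations
#'
#' Computed on the linear pg/mL scale by default (set `log10 = TRUE` to
#' correlate log-concentrations, useful when values span decades).
#' Undetermined and negative samples must be excluded by the caller.
#'
#' @param predicted,truth Numeric vectors, at least 3 quantified pairs.
#' @param log10 Correlate on the log10 scale.
#' @return Pearson's r.
#' @export
correlation_report <- function(predicted, truth, log10 = FALSE) {
  if (length(predicted) != length(truth)) abort("inputs must have equal length")
  if (length(predicted) < 3) abort("at least 3 quantified pairs required")
  if (log10) {
    predicted <- base::log10(predicted)
    truth <- base::log10(truth)
  }
  if (sd(predicted) == 0 || sd(truth) == 0) abort("zero variance input")
  cor(predicted, truth)
}

#' Duplicate-cartridge coefficient of variation
#'
#' Computes, per patient, the CV of the quantified concentrations across that
#' patient's replicate cartridges, and averages across patients. Patients
#' with fewer than 2 quantified replicates are skipped and counted.
#'
#' @param predictions A data frame with `patient_id` and `conc` (NA for
#'   non-quantified replicates).
#' @return A list with `mean_cv` (%), `per_patient` tibble, `n_skipped`.
#' @export
duplicate_cv <- function(predictions) {
  per <- predictions |>
    dplyr::filter(!is.na(.data$conc)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n = dplyr::n(),
                     cv = if (dplyr::n() >= 2) compute_cv(.data$conc) else NA_real_,
                     .groups = "drop")
  usable <- dplyr::filter(per, !is.na(.data$cv))
  n_total <- dplyr::n_distinct(predictions$patient_id)
  list(
    mean_cv = if (nrow(usable) > 0) mean(usable$cv) else NA_real_,
    per_patient = usable,
    n_skipped = n_total - nrow(usable)
  )
}

baseline_signal_col <- function(biomarker) {
  switch(biomarker,
    ckmb = feature_col("ckmb", "color"),
    ntprobnp = feature_col("ntprobnp", "color"),
    ctni = feature_col("ctni", "cl")
  )
}

#' Single-signal power-fit baseline
#'
#' The conventional curve-fitting comparator for the cascade: the biomarker's
#' designated averaged signal (colorimetric for CK-MB and NT-proBNP,
#' chemiluminescent for cTnI) is inverted through a fitted power calibration
#' model. Signals outside the model's invertible range (non-positive, or
#' mapping outside its fitted concentration span — e.g. a saturated cTnI CL
#' signal against a model fit below the saturation onset) raise an
#' out-of-range error, or yield `NA` with `on_out_of_range = "na"`.
#'
#' @param features Feature tibble.
#' @param model A `vfa_power` calibration model for the designated signal.
#' @param biomarker `"ckmb"`, `"ntprobnp"` or `"ctni"`.
#' @param on_out_of_range `"error"` (default) or `"na"`.
#' @return Concentrations in pg/mL.
#' @export
powerfit_baseline <- function(features, model, biomarker,
                              on_out_of_range = c("error", "na")) {
  on_out_of_range <- match.arg(on_out_of_range)
  biomarker <- match.arg(biomarker, .biomarkers)
  sig <- features[[baseline_signal_col(biomarker)]]
  if (is.null(sig)) abort("features lack the designated signal column")
  ok <- sig > 0
  conc <- rep(NA_real_, length(sig))
  conc[ok] <- invert_calibration(model, sig[ok])
  out_of_span <- !is.na(conc) &
    (conc < model$range[1] * 0.999 | conc > model$range[2] * 1.001)
  conc[out_of_span] <- NA
  if (on_out_of_range == "error" && any(!ok | out_of_span)) {
    abort("signal out of the baseline model's invertible range")
  }
  conc
}

#' Evaluate cascade predictions against ground truth
#'
#' Builds the per-biomarker evaluation report: range-classification accuracy
#' and confusion matrix, Pearson r between predicted and true concentrations
#' on the quantifiable subset (quantified predictions with uncensored truth;
#' undetermined and negative samples are excluded and counted separately),
#' and the duplicate-cartridge CV.
#'
#' @param predictions Output of [predict_cascade()].
#' @param truth A data frame with `sample_id`, `patient_id`,
#'   `conc_<biomarker>` and `cens_<biomarker>` columns.
#' @param log10_r Compute the correlation on log10 concentrations.
#' @return A tibble of class `vfa_report`, one row per biomarker, with a
#'   list-column `confusion`.
#' @export
evaluate_cascade <- function(predictions, truth, log10_r = FALSE) {
  out <- purrr::map_dfr(.biomarkers, function(bm) {
    pred <- dplyr::filter(predictions, .data$biomarker == bm) |>
      dplyr::left_join(truth, by = "sample_id")
    conc_true <- pred[[paste0("conc_", bm)]]
    cens <- pred[[paste0("cens_", bm)]]
    true_cls <- class_of_conc(bm, conc_true)
    true_cls[cens] <- 1L
    cls_rep <- classification_report(pred$class_range,
                                     class_labels(bm)[true_cls],
                                     labels = class_labels(bm))
    q <- !is.na(pred$conc) & !cens
    r <- if (sum(q) >= 3) correlation_report(pred$conc[q], conc_true[q],
                                             log10 = log10_r) else NA_real_
    dup <- duplicate_cv(pred[!cens, c("patient_id", "conc")])
    tibble::tibble(
      biomarker = bm,
      n = nrow(pred),
      accuracy = cls_rep$accuracy,
      pearson_r = r,
      mean_duplicate_cv = dup$mean_cv,
      n_quantified = sum(pred$status == "quantified"),
      n_negative = sum(pred$status == "negative"),
      n_undetermined = sum(pred$status == "undetermined"),
      confusion = list(cls_rep$confusion)
    )
  })
  class(out) <- c("vfa_report", class(out))
  out
}
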