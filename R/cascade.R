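# ---- the range-gated classification -> quantification cascade ----

quantifier_ranges <- function(biomarker) {
  switch(biomarker,
    ckmb = ">=500",
    ntprobnp = ">=125",
    ctni = c("<40", "40-1000", ">1000")
  )
}

model_key <- function(biomarker, range = NULL) {
  if (is.null(range)) return(paste0(biomarker, "_class"))
  suffix <- switch(range,
    ">=500" = "ge500", ">=125" = "ge125",
    "<40" = "lt40", "40-1000" = "40_1000", ">1000" = "gt1000",
    abort(sprintf("unknown range label '%s'", range))
  )
  paste0(biomarker, "_", suffix)
}

#' Train the full cascade
#'
#' Trains, per biomarker, one range classifier and one quantifier per
#' concentration range (eight networks in total): CK-MB into `<500` /
#' `>=500` pg/mL, NT-proBNP into `<125` / `>=125`, cTnI into `<40`,
#' `40-1000`, `>1000`. Ground-truth classes use closed lower bounds.
#' Samples censored below a biomarker's reporting limit contribute to that
#' biomarker's classifier (lowest class) but are excluded from its
#' quantifier training.
#'
#' @param data A data frame with the ten feature columns plus
#'   `conc_<biomarker>` and `cens_<biomarker>` truth columns (e.g. from
#'   [simulate_features()]).
#' @param seed Integer seed; each network trains with a seed derived from it.
#' @param spec_overrides Named list of overrides applied to every
#'   [model_spec()] (e.g. `list(epochs = 200)`), or a function
#'   `(spec) -> spec`.
#' @return An object of class `vfa_cascade` holding the eight `vfa_model`s.
#' @export
train_cascade <- function(data, seed = 1L, spec_overrides = NULL) {
  apply_over <- function(spec) {
    if (is.null(spec_overrides)) return(spec)
    if (is.function(spec_overrides)) return(spec_overrides(spec))
    spec[names(spec_overrides)] <- spec_overrides
    spec
  }
  models <- list()
  offset <- 0L
  for (bm in .biomarkers) {
    conc <- data[[paste0("conc_", bm)]]
    cens <- data[[paste0("cens_", bm)]]
    if (is.null(conc) || is.null(cens)) {
      abort(sprintf("data must contain conc_%s and cens_%s", bm, bm))
    }
    cls <- class_of_conc(bm, conc)
    cls[cens] <- 1L  # censored ground truth sits in the lowest class

    spec_c <- apply_over(model_spec(bm, "classifier"))
    models[[model_key(bm)]] <- train_model(spec_c, data, cls, seed = seed + offset)
    offset <- offset + 1L

    for (rg in quantifier_ranges(bm)) {
      keep <- !cens & cls == match(rg, class_labels(bm))
      if (sum(keep) < 2) {
        abort(sprintf("too few uncensored training samples for %s %s", bm, rg))
      }
      spec_q <- apply_over(model_spec(bm, "quantifier", range = rg))
      models[[model_key(bm, rg)]] <-
        train_model(spec_q, data[keep, ], conc[keep], seed = seed + offset)
      offset <- offset + 1L
    }
  }
  structure(list(models = models, seed = as.integer(seed)), class = "vfa_cascade")
}

#' Predict through the cascade with agreement-based quality assurance
#'
#' For each cartridge and biomarker the classifier assigns a concentration
#' range. CK-MB `<500` and NT-proBNP `<125` are reported negative without
#' quantification (those ranges sit wholly below the clinical cut-offs);
#' every cTnI sample is routed to the quantifier of its assigned range. A
#' quantified concentration is then cross-checked against the assigned range:
#' if it falls more than 5% outside a (finite) range boundary — below
#' `lower * 0.95` or above `upper * 1.05` — the result is labelled
#' `"undetermined"` and the concentration withheld. Bounds at 0 or infinity
#' cannot be violated.
#'
#' @param cascade A [train_cascade()] result.
#' @param features Feature tibble (one row per cartridge, must have passed
#'   quality control).
#' @return A long tibble: `sample_id` (or row number), `biomarker`,
#'   `class_range`, `status` (`"quantified"`, `"negative"`,
#'   `"undetermined"`), `conc` (pg/mL, `NA` unless quantified).
#' @export
predict_cascade <- function(cascade, features) {
  n <- nrow(features)
  ids <- features$sample_id %||% as.character(seq_len(n))
  out <- purrr::map(.biomarkers, function(bm) {
    clf <- cascade$models[[model_key(bm)]]
    cls_idx <- predict(clf, features, type = "class")
    labels <- class_labels(bm)
    class_range <- labels[cls_idx]
    status <- rep("quantified", n)
    conc <- rep(NA_real_, n)

    negative <- (bm == "ckmb" & class_range == "<500") |
      (bm == "ntprobnp" & class_range == "<125")
    status[negative] <- "negative"

    for (rg in quantifier_ranges(bm)) {
      sel <- which(!negative & class_range == rg)
      if (length(sel) == 0) next
      qm <- cascade$models[[model_key(bm, rg)]]
      if (is.null(qm)) abort(sprintf("missing quantifier for %s range %s", bm, rg))
      pred <- predict(qm, features[sel, , drop = FALSE])
      bounds <- range_bounds(bm, rg)
      bad <- (is.finite(bounds[1]) & bounds[1] > 0 & pred < bounds[1] * 0.95) |
        (is.finite(bounds[2]) & pred > bounds[2] * 1.05)
      conc[sel] <- ifelse(bad, NA_real_, pred)
      status[sel][bad] <- "undetermined"
    }
    tibble::tibble(sample_id = ids, biomarker = bm,
                   class_range = class_range, status = status, conc = conc)
  })
  dplyr::bind_rows(out)
}

#' @export
tidy.vfa_cascade <- function(x, ...) {
  purrr::map_dfr(x$models, glance)
}

#' @export
print.vfa_cascade <- function(x, ...) {
  cat("Cascade of", length(x$models), "shallow networks (seed", x$seed, ")\n")
  print(tidy(x))
  invisible(x)
}
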