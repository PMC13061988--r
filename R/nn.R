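# ---- model specifications and training of the shallow networks ----

full_feature_set <- function(biomarker) {
  if (biomarker == "ctni") {
    c(feature_col(c("ctni", "pos", "neg"), "color"),
      feature_col(c("ctni", "pos", "neg"), "cl"))
  } else {
    feature_col(c("ctni", "ntprobnp", "ckmb", "pos", "neg"), "color")
  }
}

class_labels <- function(biomarker) {
  switch(biomarker,
    ckmb = c("<500", ">=500"),
    ntprobnp = c("<125", ">=125"),
    ctni = c("<40", "40-1000", ">1000")
  )
}

# closed lower bounds: conc >= threshold belongs to the upper class
class_of_conc <- function(biomarker, conc) {
  switch(biomarker,
    ckmb = ifelse(conc >= 500, 2L, 1L),
    ntprobnp = ifelse(conc >= 125, 2L, 1L),
    ctni = ifelse(conc < 40, 1L, ifelse(conc <= 1000, 2L, 3L))
  )
}

range_bounds <- function(biomarker, label) {
  switch(paste(biomarker, label),
    "ckmb >=500" = c(500, Inf),
    "ntprobnp >=125" = c(125, Inf),
    "ctni <40" = c(0, 40),
    "ctni 40-1000" = c(40, 1000),
    "ctni >1000" = c(1000, Inf),
    abort(sprintf("unknown range '%s' for %s", label, biomarker))
  )
}

#' Specify a network of the cascade
#'
#' Builds the hyperparameter specification of one of the eight shallow fully
#' connected networks. Classifier architectures: CK-MB (128, 64, 32) hidden
#' units with dropout 0.6; NT-proBNP (64, 32) with 0.4; cTnI (128, 64) with
#' 0.4; batch normalisation with batch size 4, categorical cross-entropy,
#' Adam with initial learning rates 1e-3 / 1e-2 / 3e-3 attenuated by 0.99
#' every 10 epochs, L2 alpha 1e-3, and a fixed 2000-epoch budget keeping the
#' best-training-loss checkpoint. Quantifiers: cTnI range models (128, 64)
#' with dropout 0.1 and MSE on z-scored targets; CK-MB (128, 32), dropout
#' 0.3, MSE on targets scaled by 1/500; NT-proBNP (128, 32), dropout 0.4,
#' mean-absolute-log1p loss on targets scaled by 1/125; batch size 20,
#' initial learning rate 1e-3 halved every 50 epochs, early stopping when
#' the loss fails to improve by 1e-4 over 200 consecutive epochs (cap 5000).
#'
#' @param biomarker `"ckmb"`, `"ntprobnp"` or `"ctni"`.
#' @param stage `"classifier"` or `"quantifier"`.
#' @param range Quantifier range label (`">=500"`, `">=125"`, `"<40"`,
#'   `"40-1000"`, `">1000"`); ignored for classifiers.
#' @param ... Named overrides of any spec field (e.g. `epochs`, `features`).
#' @return A list of class `vfa_model_spec`.
#' @export
model_spec <- function(biomarker = c("ckmb", "ntprobnp", "ctni"),
                       stage = c("classifier", "quantifier"),
                       range = NULL, ...) {
  biomarker <- match.arg(biomarker)
  stage <- match.arg(stage)
  spec <- if (stage == "classifier") {
    base <- switch(biomarker,
      ckmb = list(hidden = c(128L, 64L, 32L), dropout_rate = 0.6, lr0 = 1e-3),
      ntprobnp = list(hidden = c(64L, 32L), dropout_rate = 0.4, lr0 = 1e-2),
      ctni = list(hidden = c(128L, 64L), dropout_rate = 0.4, lr0 = 3e-3)
    )
    c(base, list(
      batchnorm = TRUE, batch_size = 4L, lr_factor = 0.99, lr_period = 10L,
      loss = "cce", n_classes = length(class_labels(biomarker)),
      epochs = 2000L, early_stop = FALSE, early_tol = 1e-4, early_patience = 200L,
      target_transform = list(type = "none")
    ))
  } else {
    if (is.null(range)) abort("quantifier specs need a range label")
    range_bounds(biomarker, range)  # validates the label
    base <- switch(biomarker,
      ckmb = list(hidden = c(128L, 32L), dropout_rate = 0.3, loss = "mse",
                  target_transform = list(type = "scale", factor = 500)),
      ntprobnp = list(hidden = c(128L, 32L), dropout_rate = 0.4, loss = "rmsle",
                      target_transform = list(type = "scale", factor = 125)),
      ctni = list(hidden = c(128L, 64L), dropout_rate = 0.1, loss = "mse",
                  target_transform = list(type = "zscore"))
    )
    c(base, list(
      batchnorm = FALSE, batch_size = 20L, lr0 = 1e-3, lr_factor = 0.5,
      lr_period = 50L, n_classes = 1L,
      epochs = 5000L, early_stop = TRUE, early_tol = 1e-4, early_patience = 200L
    ))
  }
  spec$biomarker <- biomarker
  spec$stage <- stage
  spec$range <- range
  spec$l2 <- 1e-3
  spec$features <- full_feature_set(biomarker)
  over <- list(...)
  spec[names(over)] <- over
  structure(spec, class = "vfa_model_spec")
}

loss_code <- function(loss) match(loss, c("cce", "mse", "rmsle")) - 1L

transform_target <- function(tt, y, stats = NULL) {
  switch(tt$type,
    none = list(y = y, stats = NULL),
    scale = list(y = y / tt$factor, stats = NULL),
    zscore = {
      if (is.null(stats)) stats <- list(mean = mean(y), sd = max(sd(y), 1e-12))
      list(y = (y - stats$mean) / stats$sd, stats = stats)
    }
  )
}

inverse_transform_target <- function(tt, y, stats = NULL) {
  switch(tt$type,
    none = y,
    scale = y * tt$factor,
    zscore = y * stats$sd + stats$mean
  )
}

#' Train one network of the cascade
#'
#' Standardises the spec's feature subset to zero mean and unit variance
#' (statistics frozen from this training set), transforms the targets per the
#' spec, and runs the compiled Adam training loop. The returned model holds
#' the checkpoint with the lowest training loss; training is deterministic
#' under a fixed seed.
#'
#' @param spec A [model_spec()].
#' @param data A data frame containing the spec's feature columns.
#' @param target For classifiers, integer class indices (1-based) or a factor;
#'   for quantifiers, concentrations in pg/mL.
#' @param seed Integer training seed.
#' @return An object of class `vfa_model`.
#' @export
train_model <- function(spec, data, target, seed = 1L) {
  if (!all(spec$features %in% names(data))) {
    abort("data is missing feature columns required by the spec")
  }
  X <- as.matrix(data[, spec$features, drop = FALSE])
  if (any(!is.finite(X))) abort("non-finite feature values")
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")

  if (spec$stage == "classifier") {
    cls <- if (is.factor(target)) as.integer(target) else as.integer(target)
    C <- spec$n_classes
    if (!all(seq_len(C) %in% cls)) {
      abort("empty class in classifier training data")
    }
    Y <- matrix(0, nrow = length(cls), ncol = C)
    Y[cbind(seq_along(cls), cls)] <- 1
    tstats <- NULL
  } else {
    tr <- transform_target(spec$target_transform, target)
    Y <- matrix(tr$y, ncol = 1)
    tstats <- tr$stats
  }

  # the output layer starts at the location/scale of the transformed targets;
  # for the log-domain loss the geometric centre is the right location (an
  # arithmetic-scale start leaves large-target gradients, which are damped by
  # 1/(1+y'), too weak to recover within the learning-rate schedule)
  if (spec$stage == "quantifier") {
    if (spec$loss == "rmsle") {
      out_loc <- expm1(mean(log1p(Y)))
      out_scale <- max(out_loc, 1)
    } else {
      out_loc <- mean(Y)
      out_scale <- max(sd(Y), 1)
    }
  } else {
    out_loc <- 0
    out_scale <- 1
  }
  res <- nn_train_cpp(
    Xs, Y, as.integer(spec$hidden),
    rep(spec$dropout_rate, length(spec$hidden)),
    loss_code(spec$loss), spec$batchnorm, as.integer(spec$batch_size),
    spec$lr0, spec$lr_factor, as.integer(spec$lr_period), spec$l2,
    as.integer(spec$epochs), spec$early_stop, spec$early_tol,
    as.integer(spec$early_patience), out_loc, out_scale, as.integer(seed)
  )
  if (isTRUE(res$diverged)) {
    abort(paste0("training diverged (non-finite loss); trace tail: ",
                 paste(signif(utils::tail(res$trace, 5), 4), collapse = ", ")))
  }
  structure(
    list(spec = spec, params = res[c("W", "b", "gamma", "beta",
                                     "run_mean", "run_var", "batchnorm")],
         center = center, scale = scale_, target_stats = tstats,
         trace = res$trace, best_loss = res$best_loss,
         best_epoch = res$best_epoch, epochs_run = res$epochs_run,
         seed = as.integer(seed)),
    class = "vfa_model"
  )
}

#' Predict from a trained cascade network
#'
#' @param object A `vfa_model`.
#' @param newdata Data frame with the model's feature columns.
#' @param type `"response"` (concentration for quantifiers, class index for
#'   classifiers), `"prob"` (classifier class probabilities), or `"class"`.
#' @param ... Unused.
#' @return Numeric vector, or a probability matrix for `type = "prob"`.
#' @export
predict.vfa_model <- function(object, newdata, type = c("response", "prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$spec$features, drop = FALSE])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  out <- nn_predict_cpp(object$params, Xs)
  if (object$spec$stage == "classifier") {
    probs <- softmax(out)
    if (type == "prob") return(probs)
    cls <- max.col(probs, ties.method = "first")
    return(cls)
  }
  inverse_transform_target(object$spec$target_transform, drop(out),
                           object$target_stats)
}

#' @export
glance.vfa_model <- function(x, ...) {
  tibble::tibble(
    biomarker = x$spec$biomarker, stage = x$spec$stage,
    range = x$spec$range %||% NA_character_,
    best_loss = x$best_loss, best_epoch = x$best_epoch,
    epochs_run = x$epochs_run, n_features = length(x$spec$features)
  )
}

#' @export
print.vfa_model <- function(x, ...) {
  cat(sprintf("Shallow network (%s %s%s): hidden [%s], best loss %.4g at epoch %d/%d\n",
              x$spec$biomarker, x$spec$stage,
              if (is.null(x$spec$range)) "" else paste0(" ", x$spec$range),
              paste(x$spec$hidden, collapse = ", "),
              x$best_loss, x$best_epoch, x$epochs_run))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
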