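# ---- greedy iterative backward feature elimination ----

#' Backward feature elimination for one cascade model
#'
#' Starts from the model's complete feature set, trains it, then iteratively
#' removes one feature at a time from the current best-performing subset —
#' every leave-one-out candidate of the survivor is retrained and scored —
#' down to single-feature subsets. A start set of p features therefore
#' evaluates exactly `1 + p + (p-1) + ... + 2 = p(p+1)/2` subsets: the full
#' set once, then k candidates from each size-k survivor.
#' The returned subset is the global best over all
#' evaluated subsets, not just the last round. Every candidate is trained
#' with the same seed so criterion differences reflect features, not
#' initialisation. Ties prefer the smaller subset, then lexicographic order.
#'
#' @param spec A [model_spec()]; its `features` field defines the start set.
#' @param data Training data frame with the feature columns.
#' @param target Training target (see [train_model()]).
#' @param criterion `"auto"` picks training accuracy for classifiers
#'   (maximised) and the training loss for quantifiers (minimised);
#'   `"max-accuracy"` / `"min-loss"` force one.
#' @param seed Seed applied to every candidate training run.
#' @return An object of class `vfa_elimination`: `best_subset`,
#'   `best_criterion`, `criterion` name, and a `trace` tibble (one row per
#'   evaluated subset: `iteration`, `subset`, `n_features`, `value`,
#'   `survivor`).
#' @export
backward_eliminate <- function(spec, data, target,
                               criterion = c("auto", "max-accuracy", "min-loss"),
                               seed = 1L) {
  criterion <- match.arg(criterion)
  if (criterion == "auto") {
    criterion <- if (spec$stage == "classifier") "max-accuracy" else "min-loss"
  }
  maximise <- criterion == "max-accuracy"
  if (!all(spec$features %in% names(data))) {
    abort("data is missing features from the spec's full set")
  }

  score_subset <- function(subset) {
    sp <- spec
    sp$features <- subset
    m <- tryCatch(train_model(sp, data, target, seed = seed),
                  error = function(e) e)
    if (inherits(m, "error")) {
      warn(paste0("candidate {", paste(subset, collapse = ","),
                  "} failed to train: ", conditionMessage(m)))
      return(NA_real_)
    }
    if (maximise) {
      mean(predict(m, data, type = "class") == as.integer(target))
    } else {
      m$best_loss
    }
  }

  trace <- list()
  record <- function(iter, subset, value, survivor) {
    trace[[length(trace) + 1]] <<- tibble::tibble(
      iteration = iter, subset = paste(subset, collapse = "+"),
      n_features = length(subset), value = value, survivor = survivor
    )
  }

  better <- function(v, best_v) {
    if (is.na(v)) return(FALSE)
    if (is.na(best_v)) return(TRUE)
    if (maximise) v > best_v else v < best_v
  }

  current <- spec$features
  v0 <- score_subset(current)
  record(0L, current, v0, TRUE)
  all_eval <- list(list(subset = current, value = v0))

  iter <- 0L
  while (length(current) > 1) {
    iter <- iter + 1L
    candidates <- purrr::map(seq_along(current), ~ current[-.x])
    values <- purrr::map_dbl(candidates, score_subset)
    # survivor of the round: best candidate, ties by lexicographic subset id
    ord <- order(if (maximise) -values else values,
                 purrr::map_chr(candidates, paste, collapse = "+"),
                 na.last = TRUE)
    best_i <- ord[1]
    for (i in seq_along(candidates)) {
      record(iter, candidates[[i]], values[i], i == best_i)
      all_eval[[length(all_eval) + 1]] <- list(subset = candidates[[i]],
                                               value = values[i])
    }
    if (is.na(values[best_i])) {
      warn("all candidates failed in an elimination round; stopping early")
      break
    }
    current <- candidates[[best_i]]
  }

  vals <- purrr::map_dbl(all_eval, "value")
  sizes <- purrr::map_int(all_eval, ~ length(.x$subset))
  keys <- purrr::map_chr(all_eval, ~ paste(.x$subset, collapse = "+"))
  ord <- order(if (maximise) -vals else vals, sizes, keys, na.last = TRUE)
  best <- all_eval[[ord[1]]]

  structure(
    list(best_subset = best$subset, best_criterion = best$value,
         criterion = criterion, trace = dplyr::bind_rows(trace)),
    class = "vfa_elimination"
  )
}

#' Extract a feature subset from feature vectors
#'
#' @param features A feature tibble (or one-row feature vector).
#' @param subset Character vector of feature-column identifiers, in the order
#'   the model consumes them.
#' @return `features` restricted to `subset`, in subset order.
#' @export
apply_subset <- function(features, subset) {
  unknown <- setdiff(subset, names(features))
  if (length(unknown) > 0) {
    abort(paste0("unknown feature identifier(s): ", paste(unknown, collapse = ", ")))
  }
  dplyr::select(features, dplyr::all_of(subset))
}

#' @export
tidy.vfa_elimination <- function(x, ...) x$trace

#' @export
print.vfa_elimination <- function(x, ...) {
  cat(sprintf("Backward elimination (%s): best subset {%s}, criterion %.4g (%d subsets evaluated)\n",
              x$criterion, paste(x$best_subset, collapse = ", "),
              x$best_criterion, nrow(x$trace)))
  invisible(x)
}
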