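# ---- digital quality control on the control-spot channels ----

control_channels <- function() {
  c(feature_col("pos", "color"), feature_col("neg", "color"),
    feature_col("pos", "cl"), feature_col("neg", "cl"))
}

#' Fit the control-signal reference distribution
#'
#' Computes, per control channel (positive/negative control in each modality),
#' the mean and sample SD (n - 1 denominator) over a batch of cartridges.
#' Mirrors referencing the control-signal distribution across an entire study.
#'
#' @param features A feature tibble containing the four control columns.
#' @return A tibble of class `vfa_control_reference` with `channel`, `mean`,
#'   `sd`, `n`.
#' @export
fit_control_reference <- function(features) {
  chans <- control_channels()
  if (!all(chans %in% names(features))) {
    abort("features must contain the four control channels")
  }
  if (nrow(features) < 2) abort("at least 2 cartridges are required")
  out <- purrr::map_dfr(chans, function(ch) {
    tibble::tibble(channel = ch, mean = mean(features[[ch]]),
                   sd = sd(features[[ch]]), n = nrow(features))
  })
  class(out) <- c("vfa_control_reference", class(out))
  out
}

#' Three-sigma quality-control filter
#'
#' Flags a cartridge as failing quality control iff any of its four control
#' channels lies outside the closed interval `mean ± 3 sd` of the reference.
#' The interval is closed so that a channel exactly at the boundary passes
#' (pass/fail must not hinge on float rounding). Channels with `sd = 0` pass
#' only on exact equality with the reference mean.
#'
#' @param features A feature tibble (one row per cartridge).
#' @param reference A [fit_control_reference()] result; by default fitted on
#'   `features` itself (batch statistics including the cartridge under test).
#' @param leave_one_out If `TRUE`, each cartridge is tested against a
#'   reference re-fit on all other cartridges.
#' @return `features` with `qc_status` (`"pass"`/`"fail"`) and `qc_reason`
#'   (comma-separated violated channels, `NA` on pass) columns appended.
#' @export
qc_filter <- function(features, reference = NULL, leave_one_out = FALSE) {
  chans <- control_channels()
  if (leave_one_out) {
    status <- purrr::map(seq_len(nrow(features)), function(i) {
      ref <- fit_control_reference(features[-i, ])
      qc_one(features[i, ], ref, chans)
    })
  } else {
    if (is.null(reference)) reference <- fit_control_reference(features)
    status <- purrr::map(seq_len(nrow(features)), function(i) {
      qc_one(features[i, ], reference, chans)
    })
  }
  features$qc_status <- purrr::map_chr(status, "status")
  features$qc_reason <- purrr::map_chr(status, "reason")
  features
}

qc_one <- function(row, reference, chans) {
  bad <- purrr::keep(chans, function(ch) {
    r <- reference[reference$channel == ch, ]
    x <- row[[ch]]
    x < r$mean - 3 * r$sd || x > r$mean + 3 * r$sd
  })
  if (length(bad) == 0) {
    list(status = "pass", reason = NA_character_)
  } else {
    list(status = "fail", reason = paste(bad, collapse = ","))
  }
}
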