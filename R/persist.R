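# ---- persistence of references and trained cascades ----

#' Persist or restore a control reference
#'
#' The QC reference (per-channel mean/SD/n) round-trips through a small
#' key-value YAML file so a frozen reference can be applied to later batches.
#'
#' @param reference A [fit_control_reference()] result.
#' @param path File path.
#' @return `read_control_reference()` returns the reference tibble;
#'   the writer returns `path` invisibly.
#' @export
write_control_reference <- function(reference, path) {
  yaml::write_yaml(
    purrr::map(split(reference, reference$channel), function(r) {
      list(mean = r$mean, sd = r$sd, n = r$n)
    }),
    path, precision = 15
  )
  invisible(path)
}

#' @rdname write_control_reference
#' @export
read_control_reference <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- purrr::imap_dfr(raw, function(v, ch) {
    tibble::tibble(channel = ch, mean = v$mean, sd = v$sd, n = as.integer(v$n))
  })
  class(out) <- c("vfa_control_reference", class(out))
  out
}

#' Save or load a trained cascade
#'
#' Checkpoints are opaque binary files (RDS) accompanied by a plain-text YAML
#' manifest recording, per network, the architecture, feature subset,
#' standardisation statistics, target transform and training seed.
#'
#' @param cascade A [train_cascade()] result.
#' @param dir Directory to write `cascade.rds` and `manifest.yml` into.
#' @return `load_cascade()` returns the cascade; the writer returns `dir`
#'   invisibly.
#' @export
save_cascade <- function(cascade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(cascade, file.path(dir, "cascade.rds"))
  manifest <- purrr::map(cascade$models, function(m) {
    list(
      biomarker = m$spec$biomarker, stage = m$spec$stage,
      range = m$spec$range, hidden = as.list(m$spec$hidden),
      dropout = m$spec$dropout_rate, loss = m$spec$loss,
      features = as.list(m$spec$features),
      input_center = as.list(unname(m$center)),
      input_scale = as.list(unname(m$scale)),
      target_transform = m$spec$target_transform,
      target_stats = m$target_stats,
      best_loss = m$best_loss, best_epoch = m$best_epoch,
      seed = m$seed
    )
  })
  yaml::write_yaml(list(seed = cascade$seed, models = manifest),
                   file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(dir) {
  readRDS(file.path(dir, "cascade.rds"))
}
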