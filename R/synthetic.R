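# ---- synthetic cohorts, forward signal model, membrane rendering ----

# expectation of the sample SD of n normal draws is c4(n) * sigma; used to
# de-bias the replicate-CV parameterisation (see ?vfa_config)
c4_factor <- function(n) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)

# lognormal multiplicative factor with unit mean and the given relative SD
rlnorm_factor <- function(n, rel_sd) {
  if (rel_sd <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + rel_sd^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# underlying lognormal dispersion implied by a configured replicate CV (%)
replicate_rel_sd <- function(config, biomarker) {
  (config$replicate_cv[[biomarker]] / 100) / c4_factor(config$cv_ref_n)
}

#' Simulate a patient cohort of true biomarker concentrations
#'
#' Draws one concentration per biomarker per patient, log-uniform within the
#' configured range, with a configured fraction of patients falling below each
#' biomarker's reporting limit (those are flagged censored and drawn
#' log-uniform below the limit). Each patient contributes
#' `duplicates_per_sample` cartridges sharing concentrations; every cartridge
#' draws its own lognormal matrix-effect factor, the sample-level perturbation
#' serum composition applies to all its spots.
#'
#' @param config A [vfa_config()].
#' @param seed Optional integer seed; fixed seed gives identical cohorts.
#' @return A tibble with one row per cartridge: `sample_id`, `patient_id`,
#'   `replicate_id`, `conc_<biomarker>` (pg/mL), `cens_<biomarker>` (logical),
#'   `matrix_factor`.
#' @examples
#' cohort <- sample_cohort(vfa_config(n_patients = 4), seed = 1)
#' @export
sample_cohort <- function(config = vfa_config(), seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) withr::local_seed(seed)
  np <- config$n_patients
  dup <- config$duplicates_per_sample

  per_bio <- purrr::map(.biomarkers, function(bm) {
    lim <- config$reporting_limit[[bm]]
    rng <- config$conc_range[[bm]]
    cens <- runif(np) < config$censored_fraction[[bm]]
    conc <- ifelse(
      cens,
      10^runif(np, log10(lim / 100), log10(lim)),
      10^runif(np, log10(rng[1]), log10(rng[2]))
    )
    # censored draws sit strictly below the limit
    conc <- ifelse(cens, pmin(conc, lim * (1 - 1e-9)), conc)
    list(conc = conc, cens = cens)
  })
  names(per_bio) <- .biomarkers

  patients <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(np)),
    conc_ctni = per_bio$ctni$conc,
    conc_ckmb = per_bio$ckmb$conc,
    conc_ntprobnp = per_bio$ntprobnp$conc,
    cens_ctni = per_bio$ctni$cens,
    cens_ckmb = per_bio$ckmb$cens,
    cens_ntprobnp = per_bio$ntprobnp$cens
  )
  out <- tidyr::expand_grid(patients, replicate_id = seq_len(dup)) |>
    dplyr::mutate(
      sample_id = paste0(.data$patient_id, "-", .data$replicate_id),
      matrix_factor = rlnorm_factor(dplyr::n(), config$matrix_cv / 100)
    ) |>
    dplyr::select(
      "sample_id", "patient_id", "replicate_id",
      dplyr::starts_with("conc_"), dplyr::starts_with("cens_"),
      "matrix_factor"
    )
  out
}

supported_pair <- function(biomarker, modality) {
  (modality == "color" && biomarker %in% .biomarkers) ||
    (modality == "cl" && biomarker == "ctni")
}

calib_params <- function(config, biomarker, modality) {
  config$calibration[[paste0(biomarker, "_", modality)]]
}

# noise-free mean signal; cTnI/CL passes through the saturating transform:
# exact power law up to the onset, then an exponential approach to the
# plateau whose rate is fixed by slope continuity (C1 join)
forward_mean <- function(conc, biomarker, modality, config) {
  p <- calib_params(config, biomarker, modality)
  mu <- p$a * conc^p$k
  if (biomarker == "ctni" && modality == "cl") {
    xs <- config$sat_onset_ctni_cl
    P <- config$sat_plateau_ctni_cl
    s0 <- p$a * xs^p$k
    if (s0 >= P) abort("saturation plateau must exceed the signal at onset")
    lam <- p$k * s0 / (P - s0)
    hi <- conc > xs
    mu[hi] <- P - (P - s0) * (conc[hi] / xs)^(-lam)
  }
  mu[conc == 0] <- config$blank_mean
  mu
}

#' Forward concentration-to-signal model
#'
#' Evaluates the assay's forward model: a power law `a * conc^k` per supported
#' channel (CK-MB and NT-proBNP colorimetric, cTnI colorimetric, cTnI
#' chemiluminescent), with the cTnI CL channel saturating above the configured
#' onset. Zero concentration returns the blank baseline. With `noise = TRUE`
#' the signal is multiplied by a lognormal replicate factor at the configured
#' CV and by `matrix_factor`; the blank gets additive Gaussian noise instead
#' (its mean is near zero, so a relative factor is not meaningful).
#'
#' @param conc Concentration(s) in pg/mL, `>= 0`.
#' @param biomarker One of `"ctni"`, `"ckmb"`, `"ntprobnp"`.
#' @param modality `"color"` or `"cl"`.
#' @param config A [vfa_config()].
#' @param matrix_factor Multiplicative sample-level factor (default 1).
#' @param noise Draw replicate noise? Default `FALSE` (noise-free mean).
#' @return Numeric vector of absorption signals.
#' @examples
#' cfg <- vfa_config()
#' forward_signal(1e4, "ckmb", "color", cfg) # 2e-4 * (1e4)^0.6901
#' @export
forward_signal <- function(conc, biomarker, modality, config = vfa_config(),
                           matrix_factor = 1, noise = FALSE) {
  biomarker <- match.arg(biomarker, .biomarkers)
  modality <- match.arg(modality, .modalities)
  if (!supported_pair(biomarker, modality)) {
    abort(sprintf("unsupported biomarker/modality pair: %s/%s", biomarker, modality))
  }
  if (any(conc < 0)) abort("concentrations must be >= 0")
  mu <- forward_mean(conc, biomarker, modality, config)
  if (!noise) return(mu)
  rel <- replicate_rel_sd(config, biomarker)
  out <- mu * rlnorm_factor(length(mu), rel) * matrix_factor
  zero <- conc == 0
  if (any(zero)) {
    out[zero] <- config$blank_mean + rnorm(sum(zero), 0, config$blank_sd)
  }
  out
}

# one cartridge x modality: per-spot absorption signals (noisy)
draw_spot_signals <- function(sample_row, spotmap, modality, config) {
  spots <- dplyr::filter(spotmap, !is.na(.data$condition))
  mf <- sample_row$matrix_factor
  X <- purrr::map_dbl(seq_len(nrow(spots)), function(i) {
    cond <- spots$condition[i]
    if (cond == "neg") {
      config$blank_mean + rnorm(1, 0, config$blank_sd)
    } else if (cond == "pos") {
      rel <- (config$control_cv / 100) / c4_factor(config$cv_ref_n)
      config$pos_ctrl_mean * rlnorm_factor(1, rel) * mf
    } else if (supported_pair(cond, modality)) {
      conc <- sample_row[[paste0("conc_", cond)]]
      forward_signal(conc, cond, modality, config, matrix_factor = mf, noise = TRUE)
    } else {
      # no chemiluminescent label on CK-MB / NT-proBNP conjugates
      config$blank_mean + rnorm(1, 0, config$blank_sd)
    }
  })
  tibble::tibble(
    sample_id = sample_row$sample_id,
    patient_id = sample_row$patient_id,
    replicate_id = sample_row$replicate_id,
    spot_id = spots$spot_id,
    condition = spots$condition,
    modality = modality,
    X = X
  )
}

#' Forward-simulate per-spot absorption signals for a cohort
#'
#' Applies the forward model spot by spot for both modalities: test spots get
#' their biomarker's signal (chemiluminescence only for cTnI; the other
#' conjugates carry no CL label and read blank there), positive controls a
#' configured constant signal with the same noise convention, negative
#' controls the blank baseline. The cartridge matrix factor multiplies all
#' test and positive-control signals. Background-referenced intensities
#' `s = b * (1 - X)` are included so the table can feed the extraction module.
#'
#' @inheritParams sample_cohort
#' @param cohort A cohort tibble from [sample_cohort()].
#' @param spotmap A [spot_map()].
#' @return A long tibble: one row per cartridge x spot x modality with
#'   `X`, `s`, `b`.
#' @export
simulate_signals <- function(cohort, config = vfa_config(),
                             spotmap = spot_map(), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  rows <- split(cohort, seq_len(nrow(cohort)))
  out <- purrr::map(rows, function(r) {
    dplyr::bind_rows(
      draw_spot_signals(r, spotmap, "color", config),
      draw_spot_signals(r, spotmap, "cl", config)
    )
  })
  out <- dplyr::bind_rows(out)
  out$b <- config$bg_level
  out$s <- out$b * (1 - out$X)
  out
}

#' Simulate averaged feature vectors directly
#'
#' Convenience wrapper: [simulate_signals()] followed by
#' [aggregate_conditions()], returning one feature row per cartridge joined
#' with the cohort's ground truth.
#'
#' @inheritParams simulate_signals
#' @return A tibble with `sample_id`, the ten `X_<condition>_<modality>`
#'   columns, and the cohort's truth columns.
#' @export
simulate_features <- function(cohort, config = vfa_config(),
                              spotmap = spot_map(), seed = NULL) {
  spots <- simulate_signals(cohort, config, spotmap, seed = seed)
  fv <- spots |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ aggregate_conditions(.x, spotmap)) |>
    dplyr::ungroup()
  dplyr::left_join(cohort, fv, by = "sample_id")
}

#' Render a pre/post membrane image pair
#'
#' Renders the pre-assay background image (uniform intensity plus pixel noise)
#' and the post-assay image of one modality for one cartridge. Each reaction
#' spot's pixels in the modality's channel (green for colorimetric, blue for
#' CL) are set to `background * (1 - X)` for that spot's simulated absorption
#' signal; all other pixels, channels, and the vent stay at background.
#'
#' @inheritParams simulate_signals
#' @param sample_row One-row cohort tibble (a single cartridge).
#' @param modality `"color"` or `"cl"`.
#' @param offset Integer `c(dx, dy)` pixel translation applied to all spots in
#'   the post-assay image (to emulate cartridge misalignment).
#' @return A list with `bg` and `assay` (numeric `h x w x 3` arrays in
#'   [0, 1]), plus the `modality` and applied `offset`.
#' @export
render_membrane_pair <- function(sample_row, spotmap = spot_map(),
                                 modality = c("color", "cl"),
                                 config = vfa_config(), offset = c(0L, 0L),
                                 seed = NULL) {
  modality <- match.arg(modality)
  if (!is.null(seed)) withr::local_seed(seed)
  size <- config$image_size
  extent <- max(spotmap$center_x + spotmap$radius_px,
                spotmap$center_y + spotmap$radius_px)
  if (extent >= size) abort("image too small to contain all spot ROIs")

  noise_field <- function() {
    array(config$bg_level + rnorm(size * size * 3, 0, config$pixel_noise_sd),
          dim = c(size, size, 3))
  }
  bg <- noise_field()
  assay <- noise_field()
  channel <- if (modality == "color") 2L else 3L

  sig <- draw_spot_signals(sample_row, spotmap, modality, config)
  spots <- dplyr::filter(spotmap, !is.na(.data$condition))
  rowidx <- matrix(rep(0:(size - 1), times = size), nrow = size)  # y, 0-based
  colidx <- t(rowidx)                                             # x, 0-based
  for (i in seq_len(nrow(spots))) {
    cx <- spots$center_x[i] + offset[1]
    cy <- spots$center_y[i] + offset[2]
    inside <- (colidx - cx)^2 + (rowidx - cy)^2 <= spots$radius_px[i]^2
    plane <- assay[, , channel]
    level <- config$bg_level * (1 - sig$X[sig$spot_id == spots$spot_id[i]])
    plane[inside] <- level + rnorm(sum(inside), 0, config$pixel_noise_sd)
    assay[, , channel] <- plane
  }
  list(bg = bg, assay = assay, modality = modality, offset = as.integer(offset))
}

#' Write or read membrane images as PNG
#'
#' Quantises a rendered membrane image to the configured bit depth and writes
#' it as PNG (requires the `png` package). Pairs follow the naming convention
#' `<id>_bg_<modality>.png` / `<id>_assay_<modality>.png`.
#'
#' @param pair A list from [render_membrane_pair()].
#' @param dir Output directory.
#' @param id Cartridge identifier used in the file names.
#' @param bit_depth 8 or 16.
#' @return Character vector of the two paths written (invisibly).
#' @export
write_membrane_pair <- function(pair, dir, id, bit_depth = 8) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required to write images")
  }
  if (!bit_depth %in% c(8, 16)) abort("bit_depth must be 8 or 16")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  q <- function(img) {
    levels <- 2^bit_depth - 1
    round(pmin(pmax(img, 0), 1) * levels) / levels
  }
  paths <- file.path(dir, paste0(id, c("_bg_", "_assay_"), pair$modality, ".png"))
  png::writePNG(q(pair$bg), paths[1])
  png::writePNG(q(pair$assay), paths[2])
  invisible(paths)
}

#' @rdname write_membrane_pair
#' @param path PNG file path to read.
#' @export
read_membrane_image <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required to read images")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
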