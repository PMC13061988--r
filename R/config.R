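#' Generator and pipeline configuration
#'
#' Collects every tunable of the synthetic-data generator and the default
#' study conditions into one validated list. Defaults encode the assay
#' characteristics the platform reports: the printed power-law calibration
#' models per biomarker and modality, per-biomarker replicate CVs (CK-MB 3.0%,
#' NT-proBNP 1.5%, cTnI 4.5%), the chemiluminescent saturation of cTnI above
#' ~1e4 pg/mL, the cohort censoring fractions at the reference-assay reporting
#' limits (cTnI < 4 pg/mL in 20/92, CK-MB < 50 in 58/92, NT-proBNP < 10 in
#' 33/92), and duplicate cartridges per patient.
#'
#' `replicate_cv` is specified on the scale assay precision is conventionally
#' reported: the expected sample CV (in %) of a replicate set of size
#' `cv_ref_n` (default 3, triplicates). Internally the lognormal dispersion is
#' de-biased by the c4 small-sample factor so that simulated triplicates
#' reproduce the configured CV in expectation.
#'
#' @param n_patients Number of patients in a simulated cohort.
#' @param duplicates_per_sample Cartridges per patient (default 2).
#' @param calibration Named list per supported channel of `list(a, k)` forward
#'   power-model parameters (signal = a * conc^k).
#' @param sat_onset_ctni_cl,sat_plateau_ctni_cl Saturation onset (pg/mL) and
#'   absorption plateau of the cTnI chemiluminescent channel.
#' @param replicate_cv Named per-biomarker replicate CV in percent.
#' @param cv_ref_n Replicate-set size defining the CV scale (see above).
#' @param matrix_cv Sample-level matrix-effect CV in percent (one lognormal
#'   factor per cartridge, shared across its spots).
#' @param censored_fraction Named per-biomarker expected fraction of patients
#'   below the reporting limit.
#' @param reporting_limit Named per-biomarker reporting limit in pg/mL.
#' @param conc_range Named list per biomarker `c(min, max)` of the log-uniform
#'   concentration range above the reporting limit (pg/mL).
#' @param blank_mean Mean blank absorption signal at zero analyte.
#' @param blank_sd Additive SD of the blank signal (negative values allowed,
#'   mirroring real background-normalised absorptions).
#' @param pos_ctrl_mean Positive-control absorption signal (both modalities).
#' @param control_cv Replicate CV in percent of the positive-control signal.
#' @param bg_level Background image intensity level in [0, 1].
#' @param pixel_noise_sd Per-pixel Gaussian noise SD of rendered images.
#' @param image_size,bit_depth Rendered image edge length (px) and bit depth.
#' @param calibration_grid Named list per biomarker of spiked calibration
#'   concentrations (pg/mL): CK-MB 8 log-spaced points 500-1e5, NT-proBNP
#'   8 points 40-4e4, cTnI 10 points 1-1e6.
#'
#' @return A list of class `vfa_config`.
#' @examples
#' cfg <- vfa_config(n_patients = 10)
#' cfg$replicate_cv
#' @export
vfa_config <- function(
    n_patients = 92,
    duplicates_per_sample = 2,
    calibration = list(
      ckmb_color = list(a = 2e-4, k = 0.6901),
      ntprobnp_color = list(a = 1e-4, k = 0.6752),
      ctni_cl = list(a = 0.0742, k = 0.2744),
      ctni_color = list(a = 0.0179, k = 0.2739)
    ),
    sat_onset_ctni_cl = 1e4,
    sat_plateau_ctni_cl = 0.95,
    replicate_cv = c(ctni = 4.5, ckmb = 3.0, ntprobnp = 1.5),
    cv_ref_n = 3,
    matrix_cv = 7,
    censored_fraction = c(ctni = 20 / 92, ckmb = 58 / 92, ntprobnp = 33 / 92),
    reporting_limit = c(ctni = 4, ckmb = 50, ntprobnp = 10),
    conc_range = list(
      ctni = c(4, 21000), ckmb = c(50, 20000), ntprobnp = c(10, 10000)
    ),
    blank_mean = 0.01,
    blank_sd = 0.003,
    pos_ctrl_mean = 0.5,
    control_cv = 3,
    bg_level = 0.85,
    pixel_noise_sd = 0.005,
    image_size = 256,
    bit_depth = 8,
    calibration_grid = list(
      ckmb = 10^seq(log10(500), 5, length.out = 8),
      ntprobnp = 10^seq(log10(40), log10(4e4), length.out = 8),
      ctni = 10^seq(0, 6, length.out = 10)
    )) {
  cfg <- list(
    n_patients = n_patients,
    duplicates_per_sample = duplicates_per_sample,
    calibration = calibration,
    sat_onset_ctni_cl = sat_onset_ctni_cl,
    sat_plateau_ctni_cl = sat_plateau_ctni_cl,
    replicate_cv = replicate_cv,
    cv_ref_n = cv_ref_n,
    matrix_cv = matrix_cv,
    censored_fraction = censored_fraction,
    reporting_limit = reporting_limit,
    conc_range = conc_range,
    blank_mean = blank_mean,
    blank_sd = blank_sd,
    pos_ctrl_mean = pos_ctrl_mean,
    control_cv = control_cv,
    bg_level = bg_level,
    pixel_noise_sd = pixel_noise_sd,
    image_size = image_size,
    bit_depth = bit_depth,
    calibration_grid = calibration_grid
  )
  class(cfg) <- "vfa_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_patients < 1) abort("n_patients must be >= 1")
  if (any(cfg$replicate_cv <= 0)) abort("replicate CVs must be > 0")
  if (any(cfg$censored_fraction < 0 | cfg$censored_fraction > 1)) {
    abort("censored fractions must lie in [0, 1]")
  }
  if (cfg$matrix_cv < 0) abort("matrix_cv must be >= 0")
  if (cfg$sat_onset_ctni_cl <= 0) abort("saturation onset must be positive")
  invisible(cfg)
}

#' Read or write a configuration file
#'
#' Configurations round-trip through a flat YAML file so simulation conditions
#' can be versioned alongside outputs.
#'
#' @param path File path.
#' @param config A `vfa_config` object.
#' @return `read_config()` returns a `vfa_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml drops the names of atomic vectors read back as lists; re-coerce
  for (nm in c("replicate_cv", "censored_fraction", "reporting_limit")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$conc_range)) raw$conc_range <- lapply(raw$conc_range, unlist)
  if (!is.null(raw$calibration_grid)) {
    raw$calibration_grid <- lapply(raw$calibration_grid, unlist)
  }
  do.call(vfa_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "vfa_config"))
  out <- unclass(config)
  # yaml serialises named atomic vectors as plain sequences; keep the names
  for (nm in c("replicate_cv", "censored_fraction", "reporting_limit")) {
    out[[nm]] <- as.list(out[[nm]])
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
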