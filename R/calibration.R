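# ---- concentration-signal calibration: power law, 4-PL, LoB/LoD, CV ----

#' Fit a power-law calibration model
#'
#' Fits `signal = a * conc^k` by least squares of `log10(signal)` on
#' `log10(conc)` (the fit is linear, convex and reproducible on that scale,
#' the standard practice for power calibrations). The headline R^2 is
#' reported on the log-log scale; an R^2 on the linear scale is stored
#' alongside for comparisons with sigmoidal fits.
#'
#' @param points A data frame with columns `conc` (pg/mL) and `signal`, both
#'   strictly positive; at least 2 points.
#' @return An object of class `vfa_power` with elements `a`, `k`,
#'   `r.squared` (log-log), `r.squared.linear`, `range` (fitted concentration
#'   range) and `n`.
#' @examples
#' pts <- data.frame(conc = 10^(1:5), signal = 2e-4 * (10^(1:5))^0.6901)
#' fit_power(pts)
#' @export
fit_power <- function(points) {
  points <- dplyr::filter(points, TRUE)
  if (nrow(points) < 2) abort("at least 2 calibration points are required")
  if (any(points$conc <= 0) || any(points$signal <= 0)) {
    abort("power calibration requires conc > 0 and signal > 0")
  }
  lx <- log10(points$conc)
  ly <- log10(points$signal)
  fit <- lm(ly ~ lx)
  k <- unname(coef(fit)[2])
  a <- 10^unname(coef(fit)[1])
  r2 <- if (sd(ly) == 0) 1 else suppressWarnings(summary(fit)$r.squared)
  pred <- a * points$conc^k
  sst <- sum((points$signal - mean(points$signal))^2)
  r2lin <- if (sst == 0) 1 else 1 - sum((points$signal - pred)^2) / sst
  structure(
    list(form = "power", a = a, k = k, r.squared = r2, r.squared.linear = r2lin,
         range = range(points$conc), n = nrow(points)),
    class = "vfa_power"
  )
}

#' Fit a four-parameter logistic calibration model
#'
#' Fits `y = D + (A - D) / (1 + (x / C)^B)` (A: low-signal asymptote, D:
#' upper asymptote, C: inflection concentration, B: slope, sign
#' unconstrained) by Levenberg-Marquardt nonlinear least squares with
#' multi-start initialisation: quantile grid on C, logit-linearised slope for
#' B in both signs, plus a start derived from a power-law fit (which makes
#' the sigmoid at least as flexible as the power model on the same points).
#'
#' @param points A data frame with columns `conc` (> 0) and `signal`;
#'   at least 5 points spanning both flanks.
#' @return An object of class `vfa_4pl` with `A`, `B`, `C`, `D`, `r.squared`
#'   (linear scale), `range`, `n`.
#' @export
fit_4pl <- function(points) {
  if (nrow(points) < 5) abort("at least 5 calibration points are required")
  if (any(points$conc <= 0)) abort("4-PL calibration requires conc > 0")
  x <- points$conc
  y <- points$signal
  if (sd(y) == 0) abort("degenerate fit: all signals are equal")

  starts <- list()
  ylo <- min(y) - 0.01 * diff(range(y))
  yhi <- max(y) + 0.01 * diff(range(y))
  # logit-linearisation for the slope
  z <- (y - ylo) / (yhi - ylo)
  z <- pmin(pmax(z, 1e-3), 1 - 1e-3)
  b_lin <- tryCatch(
    -unname(coef(lm(log(z / (1 - z)) ~ log(x)))[2]), error = function(e) 1
  )
  for (cq in quantile(x, c(0.25, 0.5, 0.75))) {
    for (b0 in unique(c(b_lin, -b_lin, 1, -1))) {
      starts <- c(starts, list(c(A = ylo, B = b0, C = unname(cq), D = yhi)))
    }
  }
  # power-law-derived start: for x << C the 4-PL is A + (D - A) (x/C)^B
  pw <- tryCatch(fit_power(points), error = function(e) NULL)
  if (!is.null(pw) && pw$k != 0) {
    Cbig <- max(x) * 100
    starts <- c(starts, list(c(
      A = 0, B = pw$k, C = Cbig, D = pw$a * Cbig^pw$k
    )))
  }

  best <- NULL
  best_sse <- Inf
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        signal ~ D + (A - D) / (1 + (conc / C)^B),
        data = points, start = as.list(st),
        lower = c(A = -Inf, B = -Inf, C = 1e-12, D = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.finite(sse) && sse < best_sse) {
      best_sse <- sse
      best <- fit
    }
  }
  if (is.null(best)) {
    abort("4-PL fit failed to converge from all starts")
  }
  p <- as.list(coef(best))
  sst <- sum((y - mean(y))^2)
  structure(
    list(form = "fourPL", A = p$A, B = p$B, C = p$C, D = p$D,
         r.squared = 1 - best_sse / sst, range = range(x), n = length(x)),
    class = "vfa_4pl"
  )
}

#' Evaluate a calibration model forward
#'
#' @param model A `vfa_power` or `vfa_4pl` object.
#' @param conc Concentrations in pg/mL.
#' @return Predicted signals.
#' @export
predict_calibration <- function(model, conc) {
  if (inherits(model, "vfa_power")) {
    model$a * conc^model$k
  } else if (inherits(model, "vfa_4pl")) {
    model$D + (model$A - model$D) / (1 + (conc / model$C)^model$B)
  } else {
    abort("unknown calibration model")
  }
}

#' Invert a calibration model
#'
#' Maps a signal back to the unique concentration producing it. Power models
#' invert in closed form for any positive signal (if `k > 0`); 4-PL models
#' invert on the open interval between their asymptotes and raise an
#' out-of-range error elsewhere (e.g. at or above the plateau).
#'
#' @param model A `vfa_power` or `vfa_4pl` object.
#' @param signal Signal value(s) to invert.
#' @return Concentration(s) in pg/mL.
#' @export
invert_calibration <- function(model, signal) {
  if (inherits(model, "vfa_power")) {
    if (model$k == 0) abort("constant power model is not invertible")
    if (any(signal <= 0)) abort("signal out of invertible range (must be > 0)")
    (signal / model$a)^(1 / model$k)
  } else if (inherits(model, "vfa_4pl")) {
    lo <- min(model$A, model$D); hi <- max(model$A, model$D)
    if (any(signal <= lo) || any(signal >= hi)) {
      abort("signal out of invertible range (outside the 4-PL asymptotes)")
    }
    model$C * ((model$A - signal) / (signal - model$D))^(1 / model$B)
  } else {
    abort("unknown calibration model")
  }
}

#' Limits of blank and detection
#'
#' Computes the limit of blank as `mean + 1.645 * SD` of the blank signals,
#' converted to concentration through the calibration model, and the limit of
#' detection as `LoB + 1.645 * SD` of the lowest-concentration replicate
#' measurements, with each replicate signal inverted to concentration units
#' first (both terms live in concentration space before combining).
#'
#' @param blank_signals Numeric vector of blank-sample signals (>= 3).
#' @param low_signals Numeric vector of replicate signals at the lowest
#'   measured concentration (>= 3).
#' @param model An invertible calibration model.
#' @return A one-row tibble with `lob` and `lod` in pg/mL and the replicate
#'   SD in concentration units (`sd_low_conc`).
#' @export
compute_limits <- function(blank_signals, low_signals, model) {
  if (length(blank_signals) < 3) abort("at least 3 blank measurements required")
  if (length(low_signals) < 3) abort("at least 3 low-concentration replicates required")
  lob_signal <- mean(blank_signals) + 1.645 * sd(blank_signals)
  lob <- invert_calibration(model, lob_signal)
  low_conc <- invert_calibration(model, low_signals)
  lod <- lob + 1.645 * sd(low_conc)
  tibble::tibble(lob = lob, lod = lod, sd_low_conc = sd(low_conc))
}

#' Coefficient of variation
#'
#' `100 * SD / mean` with the sample SD (n - 1 denominator).
#'
#' @param x Numeric vector of replicate values (>= 2, nonzero mean).
#' @return CV in percent.
#' @examples
#' compute_cv(c(9, 11)) # 14.14
#' @export
compute_cv <- function(x) {
  if (length(x) < 2) abort("at least 2 replicates required")
  m <- mean(x)
  if (m == 0) abort("CV undefined for zero mean")
  100 * sd(x) / m
}

# ---- broom-style methods ----

#' @export
tidy.vfa_power <- function(x, ...) {
  tibble::tibble(term = c("a", "k"), estimate = c(x$a, x$k))
}

#' @export
tidy.vfa_4pl <- function(x, ...) {
  tibble::tibble(term = c("A", "B", "C", "D"),
                 estimate = c(x$A, x$B, x$C, x$D))
}

#' @export
glance.vfa_power <- function(x, ...) {
  tibble::tibble(r.squared = x$r.squared, r.squared.linear = x$r.squared.linear,
                 n = x$n, conc_min = x$range[1], conc_max = x$range[2])
}

#' @export
glance.vfa_4pl <- function(x, ...) {
  tibble::tibble(r.squared = x$r.squared, n = x$n,
                 conc_min = x$range[1], conc_max = x$range[2])
}

#' @export
print.vfa_power <- function(x, ...) {
  cat(sprintf("Power calibration: signal = %.4g * conc^%.4f (R^2 log-log = %.4f, n = %d)\n",
              x$a, x$k, x$r.squared, x$n))
  invisible(x)
}

#' @export
print.vfa_4pl <- function(x, ...) {
  cat(sprintf("4-PL calibration: A = %.4g, B = %.4g, C = %.4g, D = %.4g (R^2 = %.4f, n = %d)\n",
              x$A, x$B, x$C, x$D, x$r.squared, x$n))
  invisible(x)
}
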