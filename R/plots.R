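# ---- ggplot2 views of the result types ----

#' @export
autoplot.vfa_power <- function(object, points = NULL, n = 200, ...) {
  grid <- tibble::tibble(
    conc = 10^seq(log10(object$range[1]), log10(object$range[2]), length.out = n)
  )
  grid$signal <- predict_calibration(object, grid$conc)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$conc, y = .data$signal)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (pg/mL)", y = "Absorption signal",
                  title = sprintf("signal = %.3g conc^%.4f", object$a, object$k))
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points, alpha = 0.7)
  }
  p
}

#' @export
autoplot.vfa_4pl <- function(object, points = NULL, n = 200, ...) {
  grid <- tibble::tibble(
    conc = 10^seq(log10(object$range[1]), log10(object$range[2]), length.out = n)
  )
  grid$signal <- predict_calibration(object, grid$conc)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$conc, y = .data$signal)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (pg/mL)", y = "Signal",
                  title = "Four-parameter logistic calibration")
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points, alpha = 0.7)
  }
  p
}

#' @export
autoplot.vfa_elimination <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$n_features, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$survivor), alpha = 0.8) +
    ggplot2::scale_x_reverse(breaks = unique(tr$n_features)) +
    ggplot2::labs(x = "Features retained", y = object$criterion,
                  title = "Backward feature elimination trace")
}

#' @export
autoplot.vfa_pipeline <- function(object, ...) {
  truth_cols <- purrr::map_dfr(.biomarkers, function(bm) {
    test <- dplyr::filter(object$features,
                          .data$sample_id %in% object$test_ids)
    dplyr::filter(object$predictions, .data$biomarker == bm,
                  .data$status == "quantified") |>
      dplyr::left_join(test, by = "sample_id") |>
      dplyr::transmute(biomarker = bm, predicted = .data$conc,
                       truth = .data[[paste0("conc_", bm)]],
                       censored = .data[[paste0("cens_", bm)]])
  })
  ggplot2::ggplot(dplyr::filter(truth_cols, !.data$censored),
                  ggplot2::aes(x = .data$truth, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~biomarker, scales = "free") +
    ggplot2::labs(x = "True concentration (pg/mL)",
                  y = "Cascade prediction (pg/mL)")
}

#' Display a rendered membrane image
#'
#' @param pair A [render_membrane_pair()] result.
#' @param which `"assay"` or `"bg"`.
#' @return A ggplot object rasterising the image.
#' @export
plot_membrane <- function(pair, which = c("assay", "bg")) {
  which <- match.arg(which)
  img <- pair[[which]]
  df <- tibble::tibble(x = 0, y = 0)
  ggplot2::ggplot(df) +
    ggplot2::annotation_raster(img, xmin = 0, xmax = ncol(img),
                               ymin = 0, ymax = nrow(img)) +
    ggplot2::xlim(0, ncol(img)) + ggplot2::ylim(0, nrow(img)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(which, " (", pair$modality, ")"))
}
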