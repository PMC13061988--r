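# ---- image registration, spot intensities, absorption normalisation ----

image_channel <- function(image, modality) {
  if (length(dim(image)) == 3) {
    image[, , if (modality == "color") 2L else 3L]
  } else {
    image
  }
}

#' Locate spot regions of interest by template registration
#'
#' Finds the circular regions of interest at the layout's nominal centres
#' after rigid integer-pixel registration: the binary spot template is slid
#' over the image and the shift minimising the mean intensity inside the spot
#' masks (spots absorb, so they are dark) is taken. The membrane geometry is
#' fixed by fabrication, so template registration is preferred over blob
#' detection, which fails at low signal.
#'
#' If the image carries no spot contrast (all-background image), registration
#' falls back to the nominal grid with a warning. A best shift on the search
#' boundary is treated as a segmentation failure.
#'
#' @param image Numeric matrix or `h x w x 3` array in [0, 1].
#' @param spotmap A [spot_map()].
#' @param modality `"color"` (green channel) or `"cl"` (blue channel).
#' @param max_shift Maximum allowed registration shift in pixels.
#' @param roi_scale Measurement ROI radius as a fraction of the printed spot
#'   radius (default 0.7, avoiding wax-edge pixels).
#' @param min_contrast Minimum depth (background units) between the median and
#'   best registration score below which the image is treated as blank.
#' @return A tibble of reaction-spot ROIs (`spot_id`, `condition`, `center_x`,
#'   `center_y`, `radius`) with the recovered shift in `attr(, "shift")`.
#' @export
locate_spots <- function(image, spotmap, modality = c("color", "cl"),
                         max_shift = 10L, roi_scale = 0.7,
                         min_contrast = 1e-3) {
  modality <- match.arg(modality)
  ch <- image_channel(image, modality)
  h <- nrow(ch); w <- ncol(ch)
  spots <- dplyr::filter(spotmap, !is.na(.data$condition))
  extent <- max(spots$center_x + spots$radius_px, spots$center_y + spots$radius_px)
  if (extent >= min(h, w)) abort("image dimensions are smaller than the spot map extent")

  # linear pixel indices of the nominal template masks (1-based, column-major)
  rowidx <- matrix(rep(seq_len(h) - 1L, times = w), nrow = h)
  colidx <- matrix(rep(seq_len(w) - 1L, each = h), nrow = h)
  # the registration template uses the full printed radius: a shrunken mask
  # sits flat inside the spot and leaves small shifts tied up to noise
  template <- logical(h * w)
  for (i in seq_len(nrow(spots))) {
    inside <- (colidx - spots$center_x[i])^2 + (rowidx - spots$center_y[i])^2 <=
      spots$radius_px[i]^2
    template[inside] <- TRUE
  }
  base_idx <- which(template)

  shifts <- tidyr::expand_grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
  score <- purrr::map_dbl(seq_len(nrow(shifts)), function(i) {
    idx <- base_idx + shifts$dy[i] + shifts$dx[i] * h
    idx <- idx[idx >= 1 & idx <= h * w]
    mean(ch[idx])
  })
  best <- which.min(score)
  depth <- median(score) - score[best]
  if (depth < min_contrast) {
    warn("no spot contrast detected; falling back to the nominal grid")
    dx <- 0L; dy <- 0L
  } else {
    dx <- shifts$dx[best]; dy <- shifts$dy[best]
    if (abs(dx) >= max_shift || abs(dy) >= max_shift) {
      abort("segmentation failure: registration shift exceeds the allowed bound")
    }
  }
  out <- tibble::tibble(
    spot_id = spots$spot_id,
    condition = spots$condition,
    center_x = spots$center_x + dx,
    center_y = spots$center_y + dy,
    radius = roi_scale * spots$radius_px
  )
  attr(out, "shift") <- c(dx = dx, dy = dy)
  out
}

#' Measure mean spot intensities in a pre/post image pair
#'
#' Averages the modality's channel (green for colorimetric, blue for
#' chemiluminescent) over each ROI's pixels in both the pre-assay background
#' image and the post-assay image. All ROI pixels contribute unweighted; no
#' outlier rejection is applied.
#'
#' @param bg_image,assay_image Images of identical shape (matrix or
#'   `h x w x 3` array).
#' @param rois ROI tibble from [locate_spots()].
#' @param modality `"color"` or `"cl"`.
#' @return A tibble (`spot_id`, `condition`, `modality`, `s`, `b`) with the
#'   post-assay (`s`) and background (`b`) mean intensities.
#' @export
measure_intensities <- function(bg_image, assay_image, rois,
                                modality = c("color", "cl")) {
  modality <- match.arg(modality)
  if (!identical(dim(bg_image), dim(assay_image))) {
    abort("background and assay images must have the same shape")
  }
  bg <- image_channel(bg_image, modality)
  as_ <- image_channel(assay_image, modality)
  h <- nrow(bg); w <- ncol(bg)
  rowidx <- matrix(rep(seq_len(h) - 1L, times = w), nrow = h)
  colidx <- matrix(rep(seq_len(w) - 1L, each = h), nrow = h)

  res <- purrr::map(seq_len(nrow(rois)), function(i) {
    cx <- rois$center_x[i]; cy <- rois$center_y[i]; r <- rois$radius[i]
    if (cx - r < 0 || cy - r < 0 || cx + r > w - 1 || cy + r > h - 1) {
      abort("ROI falls outside the image bounds")
    }
    inside <- (colidx - cx)^2 + (rowidx - cy)^2 <= r^2
    list(s = mean(as_[inside]), b = mean(bg[inside]))
  })
  tibble::tibble(
    spot_id = rois$spot_id,
    condition = rois$condition,
    modality = modality,
    s = purrr::map_dbl(res, "s"),
    b = purrr::map_dbl(res, "b")
  )
}

#' Background-normalised absorption signal
#'
#' Computes the absorption signal `X = 1 - s / b` from a post-assay spot
#' intensity `s` and its pre-assay background intensity `b`. Values above the
#' background (`s > b`) give negative `X` and are retained as-is so downstream
#' quality control and models see the raw distribution.
#'
#' @param s,b Numeric vectors of post-assay and background intensities; `b`
#'   must be strictly positive.
#' @return Numeric vector of absorption signals (`<= 1`).
#' @examples
#' normalize_signal(c(0.5, 1.1), c(1, 1)) # 0.5, -0.1
#' @export
normalize_signal <- function(s, b) {
  if (any(b <= 0)) abort("invalid background: b must be > 0")
  1 - s / b
}

#' Average alike spots into the ten-element feature vector
#'
#' Averages the per-spot absorption signals of each immunoreaction condition
#' (along the spot repeats) for each modality, producing the 5 x 2 = 10
#' averaged absorption signals of one cartridge.
#'
#' @param spot_values A long tibble with columns `condition`, `modality`, `X`
#'   for a single cartridge (e.g. from [simulate_signals()] or built from
#'   [measure_intensities()] + [normalize_signal()]).
#' @param spotmap A [spot_map()] (defines the expected conditions).
#' @return A one-row tibble with the ten `X_<condition>_<modality>` columns.
#' @export
aggregate_conditions <- function(spot_values, spotmap = spot_map()) {
  need <- tidyr::expand_grid(condition = .conditions, modality = .modalities)
  got <- dplyr::distinct(spot_values, .data$condition, .data$modality)
  missing <- dplyr::anti_join(need, got, by = c("condition", "modality"))
  if (nrow(missing) > 0) {
    abort(paste0(
      "incomplete cartridge: missing condition(s) ",
      paste(feature_col(missing$condition, missing$modality), collapse = ", ")
    ))
  }
  if (any(!is.finite(spot_values$X))) abort("non-finite absorption signal")
  wide <- spot_values |>
    dplyr::group_by(.data$condition, .data$modality) |>
    dplyr::summarise(X = mean(.data$X), .groups = "drop") |>
    dplyr::mutate(name = feature_col(.data$condition, .data$modality)) |>
    dplyr::select("name", "X") |>
    tidyr::pivot_wider(names_from = "name", values_from = "X")
  dplyr::select(wide, dplyr::all_of(feature_cols()))
}

#' Extract a cartridge's feature vector from its image pairs
#'
#' End-to-end extraction for one cartridge: registers the layout on each
#' post-assay image, measures spot intensities against the pre-assay
#' background, normalises them to absorption signals and averages alike spots.
#'
#' @param bg_color,assay_color Colorimetric pre/post images.
#' @param bg_cl,assay_cl Chemiluminescent pre/post images.
#' @inheritParams locate_spots
#' @return A one-row tibble with the ten feature columns; the per-modality
#'   registration shifts are attached as `attr(, "shifts")`.
#' @export
extract_features <- function(bg_color, assay_color, bg_cl, assay_cl,
                             spotmap = spot_map(), max_shift = 10L,
                             roi_scale = 0.7) {
  per_mod <- purrr::map2(
    list(color = list(bg_color, assay_color), cl = list(bg_cl, assay_cl)),
    .modalities,
    function(imgs, mod) {
      rois <- locate_spots(imgs[[2]], spotmap, mod,
                           max_shift = max_shift, roi_scale = roi_scale)
      ints <- measure_intensities(imgs[[1]], imgs[[2]], rois, mod)
      ints$X <- normalize_signal(ints$s, ints$b)
      list(ints = ints, shift = attr(rois, "shift"))
    }
  )
  spot_values <- dplyr::bind_rows(per_mod$color$ints, per_mod$cl$ints)
  out <- aggregate_conditions(spot_values, spotmap)
  attr(out, "shifts") <- list(color = per_mod$color$shift, cl = per_mod$cl$shift)
  out
}

#' Build feature vectors from a per-spot intensity table
#'
#' Alternative entry point when raw intensities are tabulated rather than
#' imaged: a table with `cartridge_id`, `spot_id`, `modality`, `s`, `b` is
#' normalised and aggregated per cartridge.
#'
#' @param spot_table The per-spot intensity table.
#' @param spotmap A [spot_map()] used to assign conditions to spot ids.
#' @return A tibble with `cartridge_id` and the ten feature columns.
#' @export
extract_features_from_table <- function(spot_table, spotmap = spot_map()) {
  conds <- dplyr::select(spotmap, "spot_id", "condition")
  spot_table |>
    dplyr::left_join(conds, by = "spot_id") |>
    dplyr::mutate(X = normalize_signal(.data$s, .data$b)) |>
    dplyr::group_by(.data$cartridge_id) |>
    dplyr::group_modify(~ aggregate_conditions(.x, spotmap)) |>
    dplyr::ungroup()
}
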