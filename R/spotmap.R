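#' Sensing-membrane spot layout
#'
#' Builds the geometric and semantic layout of the multiplexed sensing
#' membrane: 16 reaction spots on a 4x4 grid plus one non-reaction vent spot.
#' The condition multiplicities are fixed by the membrane design: four cTnI
#' spots, three CK-MB, three NT-proBNP, two positive controls (anti-IgG,
#' universal signal) and four negative controls (buffer only).
#'
#' @param image_size Edge length in pixels of the (square) membrane image the
#'   layout is embedded in.
#' @param pitch_px Centre-to-centre spot spacing in pixels.
#' @param radius_px Printed spot radius in pixels. Regions of interest used for
#'   intensity measurement default to 0.7 of this radius to avoid wax-edge
#'   pixels (see [locate_spots()]).
#'
#' @return A tibble with one row per spot: `spot_id` (1-16, vent = 17), `row`,
#'   `col` grid indices (vent has `NA`), `center_x`, `center_y` (0-based pixel
#'   coordinates, origin top-left), `radius_px`, and `condition` (one of
#'   `"ctni"`, `"ckmb"`, `"ntprobnp"`, `"pos"`, `"neg"`, or `NA` for the vent).
#'
#' @examples
#' sm <- spot_map()
#' dplyr::count(sm, condition)
#' @export
spot_map <- function(image_size = 256, pitch_px = 48, radius_px = 14) {
  # row-major condition assignment over the 4x4 grid
  cond <- c(
    "neg",  "ckmb", "ckmb", "neg",
    "ntprobnp", "ctni", "ctni", "ntprobnp",
    "ntprobnp", "ctni", "ctni", "ckmb",
    "neg",  "pos",  "pos",  "neg"
  )
  offset <- (image_size - 3 * pitch_px) / 2
  grid <- tidyr::expand_grid(row = 1:4, col = 1:4)
  out <- tibble::tibble(
    spot_id = 1:16,
    row = grid$row,
    col = grid$col,
    center_x = offset + (grid$col - 1) * pitch_px,
    center_y = offset + (grid$row - 1) * pitch_px,
    radius_px = radius_px,
    condition = cond
  )
  vent <- tibble::tibble(
    spot_id = 17L, row = NA_integer_, col = NA_integer_,
    center_x = image_size - offset / 2, center_y = image_size - offset / 2,
    radius_px = radius_px / 2, condition = NA_character_
  )
  out <- dplyr::bind_rows(out, vent)
  validate_spot_map(out)
  out
}

#' Validate a spot layout
#'
#' Checks the structural invariants of a membrane layout: exactly 16 reaction
#' spots with the fixed condition multiplicities (cTnI 4, CK-MB 3, NT-proBNP 3,
#' positive control 2, negative control 4), pairwise-disjoint regions of
#' interest, and a vent spot carrying no condition.
#'
#' @param spotmap A tibble as returned by [spot_map()].
#' @return `spotmap`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_spot_map <- function(spotmap) {
  reaction <- dplyr::filter(spotmap, !is.na(.data$condition))
  if (nrow(reaction) != 16L) {
    abort("spot map must contain exactly 16 reaction spots")
  }
  mult <- table(reaction$condition)
  want <- c(ckmb = 3L, ctni = 4L, neg = 4L, ntprobnp = 3L, pos = 2L)
  if (!identical(as.integer(mult[names(want)]), unname(want))) {
    abort("condition multiplicities must be cTnI=4, CK-MB=3, NT-proBNP=3, pos=2, neg=4")
  }
  # pairwise-disjoint ROIs
  n <- nrow(spotmap)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- sqrt((spotmap$center_x[i] - spotmap$center_x[j])^2 +
                  (spotmap$center_y[i] - spotmap$center_y[j])^2)
      if (d <= spotmap$radius_px[i] + spotmap$radius_px[j]) {
        abort("spot regions of interest overlap")
      }
    }
  }
  invisible(spotmap)
}
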