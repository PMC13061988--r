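test_that("normalization follows the absorption definition and retains negatives", {
  expect_equal(normalize_signal(1, 1), 0)
  expect_equal(normalize_signal(0.5, 1), 0.5)
  expect_equal(normalize_signal(1.1, 1), -0.1)
  expect_equal(normalize_signal(c(2, 1), c(4, 2)), c(0.5, 0.5))
  expect_error(normalize_signal(1, 0), "invalid background")
  expect_error(normalize_signal(1, -1), "invalid background")
})

test_that("intensity measurement is the unweighted ROI mean of the channel", {
  sm <- spot_map()
  size <- 256
  uniform <- array(100 / 255, dim = c(size, size, 3))
  # blank image: nominal grid fallback (warns, tested elsewhere)
  rois <- suppressWarnings(locate_spots(uniform, sm, "color"))
  ints <- measure_intensities(uniform, uniform, rois, "color")
  expect_true(all(abs(ints$s - 100 / 255) < 1e-12))
  # half-and-half ROI: mean contract
  half <- uniform
  half[, 1:(size / 2), 2] <- 200 / 255
  left_roi <- rois[which.min(rois$center_x), ]
  expect_true(left_roi$center_x + left_roi$radius < size / 2)
  v <- measure_intensities(uniform, half, left_roi, "color")
  expect_equal(v$s, 200 / 255)
  split_roi <- left_roi
  split_roi$center_x <- size / 2 - 0.5  # straddles the boundary evenly
  v2 <- measure_intensities(uniform, half, split_roi, "color")
  expect_equal(v2$s, 150 / 255, tolerance = 1e-9)
})

test_that("ROI outside the image bounds errors", {
  sm <- spot_map()
  img <- array(0.5, dim = c(256, 256, 3))
  roi <- tibble::tibble(spot_id = 1L, condition = "ctni",
                        center_x = 254, center_y = 128, radius = 10)
  expect_error(measure_intensities(img, img, roi, "color"), "outside")
  expect_error(
    measure_intensities(img, array(0.5, dim = c(128, 128, 3)),
                        roi, "color"),
    "same shape"
  )
})

test_that("registration recovers a known translation and flags blanks", {
  cfg <- vfa_config(n_patients = 1)
  sm <- spot_map()
  coh <- sample_cohort(cfg, seed = 21)
  pair <- render_membrane_pair(coh[1, ], sm, "color", cfg,
                               offset = c(3L, -2L), seed = 22)
  rois <- locate_spots(pair$assay, sm, "color")
  expect_equal(unname(attr(rois, "shift")), c(3L, -2L))

  expect_warning(
    rois0 <- locate_spots(pair$bg, sm, "color"),
    "falling back"
  )
  expect_equal(unname(attr(rois0, "shift")), c(0L, 0L))
})

test_that("aggregation averages alike spots and is permutation invariant", {
  sm <- spot_map()
  base <- dplyr::filter(sm, !is.na(condition))[, c("spot_id", "condition")]
  vals <- tidyr::expand_grid(base, modality = c("color", "cl"))
  vals$X <- 0.2
  vals$X[vals$condition == "ctni" & vals$modality == "color"] <-
    c(0.10, 0.12, 0.11, 0.11)
  fv <- aggregate_conditions(vals, sm)
  expect_equal(ncol(fv), 10L)
  expect_equal(fv$X_ctni_color, 0.11)
  expect_equal(fv$X_pos_cl, 0.2)

  shuffled <- vals[withr::with_seed(1, sample(nrow(vals))), ]
  expect_equal(aggregate_conditions(shuffled, sm), fv)

  # all spots equal => all averaged signals equal
  vals$X <- 0.3
  fv2 <- aggregate_conditions(vals, sm)
  expect_true(all(unlist(fv2) == 0.3))

  # missing condition errors
  expect_error(
    aggregate_conditions(dplyr::filter(vals, condition != "pos"), sm),
    "incomplete cartridge"
  )
})

test_that("aggregation matches exact per-condition means from the generator", {
  cfg <- tiny_config()
  coh <- sample_cohort(cfg, seed = 31)
  spots <- simulate_signals(coh, cfg, seed = 32)
  one <- dplyr::filter(spots, sample_id == coh$sample_id[1])
  fv <- aggregate_conditions(one, spot_map())
  manual <- mean(one$X[one$condition == "ckmb" & one$modality == "color"])
  expect_equal(fv$X_ckmb_color, manual, tolerance = 1e-12)
})

test_that("render -> extract round trip recovers the programmed signals", {
  cfg <- vfa_config(n_patients = 1, pixel_noise_sd = 0.004)
  sm <- spot_map()
  coh <- sample_cohort(cfg, seed = 41)
  pc <- render_membrane_pair(coh[1, ], sm, "color", cfg, seed = 42)
  pl <- render_membrane_pair(coh[1, ], sm, "cl", cfg, seed = 43)
  fv <- extract_features(pc$bg, pc$assay, pl$bg, pl$assay, sm)
  expect_equal(ncol(fv), 10L)

  # reference: noise-free programmed means for the same cartridge
  mu_ckmb <- forward_signal(coh$conc_ckmb[1], "ckmb", "color", cfg) *
    coh$matrix_factor[1]
  # ROI-mean pixel noise is tiny; replicate noise dominates the tolerance
  rel <- cfg$replicate_cv[["ckmb"]] / 100 * 4
  expect_lt(abs(fv$X_ckmb_color - mu_ckmb), rel * mu_ckmb + 0.01)
  # extracted signals equal the rendered per-spot absorptions within
  # 2 pixel-noise SDs of an ROI mean (the sharp oracle)
  rois <- locate_spots(pc$assay, sm, "color")
  ints <- measure_intensities(pc$bg, pc$assay, rois, "color")
  X <- normalize_signal(ints$s, ints$b)
  n_px <- pi * (0.7 * 14)^2
  tol <- 2 * (cfg$pixel_noise_sd / cfg$bg_level) * sqrt(2 / n_px)
  expect_equal(fv$X_ckmb_color, mean(X[ints$condition == "ckmb"]),
               tolerance = 1e-12)
  expect_true(all(abs(X) <= 1))
  expect_lt(abs(mean(X[ints$condition == "neg"]) - cfg$blank_mean), 10 * tol + 0.01)
})

test_that("per-spot intensity tables reproduce image-free extraction", {
  cfg <- tiny_config()
  coh <- sample_cohort(cfg, seed = 51)
  spots <- simulate_signals(coh, cfg, seed = 52)
  tab <- dplyr::transmute(spots, cartridge_id = sample_id, spot_id,
                          modality, s, b)
  fv <- extract_features_from_table(tab)
  expect_equal(nrow(fv), nrow(coh))
  one <- dplyr::filter(spots, sample_id == coh$sample_id[1],
                       condition == "ctni", modality == "cl")
  expect_equal(fv$X_ctni_cl[fv$cartridge_id == coh$sample_id[1]],
               mean(one$X), tolerance = 1e-12)
})
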