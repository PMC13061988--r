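test_that("cohort duplication and seeding contracts hold", {
  cfg <- vfa_config(n_patients = 1, duplicates_per_sample = 2)
  coh <- sample_cohort(cfg, seed = 3)
  expect_equal(nrow(coh), 2L)
  expect_equal(coh$conc_ctni[1], coh$conc_ctni[2])
  expect_equal(coh$conc_ckmb[1], coh$conc_ckmb[2])
  expect_equal(coh$patient_id[1], coh$patient_id[2])

  cfg2 <- vfa_config(n_patients = 20)
  a <- sample_cohort(cfg2, seed = 11)
  b <- sample_cohort(cfg2, seed = 11)
  c <- sample_cohort(cfg2, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("censored fractions match the configured cohort composition", {
  cfg <- vfa_config(n_patients = 92, duplicates_per_sample = 1)
  n_cens <- withr::with_seed(99, {
    reps <- purrr::map_int(1:40, function(i) {
      sum(sample_cohort(cfg)$cens_ctni)
    })
    reps
  })
  # binomial mean 20, SE of the mean over 40 cohorts = sqrt(92*p*(1-p)/40)
  p <- 20 / 92
  se <- sqrt(92 * p * (1 - p) / 40)
  expect_lt(abs(mean(n_cens) - 20), 3 * se)
  coh <- sample_cohort(cfg, seed = 4)
  expect_true(all(coh$conc_ckmb[coh$cens_ckmb] < 50))
  expect_true(all(coh$conc_ntprobnp[coh$cens_ntprobnp] < 10))
})

test_that("invalid generator settings are rejected", {
  expect_error(vfa_config(censored_fraction = c(ctni = 1.2, ckmb = 0, ntprobnp = 0)),
               "\\[0, 1\\]")
  expect_error(vfa_config(replicate_cv = c(ctni = 0, ckmb = 3, ntprobnp = 1.5)),
               "> 0")
  expect_error(vfa_config(n_patients = 0), "n_patients")
})

test_that("noise-free forward model reproduces the printed calibration curves", {
  cfg <- vfa_config()
  expect_equal(forward_signal(1e4, "ckmb", "color", cfg), 2e-4 * 1e4^0.6901)
  expect_equal(forward_signal(1e4, "ckmb", "color", cfg), 0.115, tolerance = 5e-3)
  expect_equal(forward_signal(1e3, "ntprobnp", "color", cfg), 1e-4 * 1e3^0.6752)
  expect_equal(forward_signal(100, "ctni", "cl", cfg), 0.0742 * 100^0.2744)
  expect_equal(forward_signal(100, "ctni", "color", cfg), 0.0179 * 100^0.2739)
  expect_equal(forward_signal(0, "ckmb", "color", cfg), cfg$blank_mean)
})

test_that("unsupported channel pairs and negative concentrations error", {
  cfg <- vfa_config()
  expect_error(forward_signal(10, "ckmb", "cl", cfg), "unsupported")
  expect_error(forward_signal(10, "ntprobnp", "cl", cfg), "unsupported")
  expect_error(forward_signal(-1, "ctni", "cl", cfg), ">= 0")
})

test_that("cTnI CL channel saturates while the colorimetric channel keeps rising", {
  cfg <- vfa_config()
  cl <- forward_signal(c(1e5, 1e6), "ctni", "cl", cfg)
  expect_lt(abs(cl[2] - cl[1]), 0.05 * cfg$sat_plateau_ctni_cl)
  col <- forward_signal(c(1e5, 1e6), "ctni", "color", cfg)
  expect_gt(col[2], col[1] * 1.5)
  # exact power law below the onset, continuous at it
  expect_equal(forward_signal(9999, "ctni", "cl", cfg), 0.0742 * 9999^0.2744)
  onset <- cfg$sat_onset_ctni_cl
  expect_equal(forward_signal(onset * (1 + 1e-9), "ctni", "cl", cfg),
               forward_signal(onset, "ctni", "cl", cfg), tolerance = 1e-6)
})

test_that("noise-free forward model is strictly monotone before saturation", {
  cfg <- vfa_config()
  grids <- list(
    ckmb = 10^seq(log10(50), 5, length.out = 50),
    ntprobnp = 10^seq(1, log10(4e4), length.out = 50),
    ctni = 10^seq(0, 6, length.out = 50)
  )
  for (bm in c("ckmb", "ntprobnp", "ctni")) {
    y <- forward_signal(grids[[bm]], bm, "color", cfg)
    expect_true(all(diff(y) > 0), info = paste(bm, "color"))
  }
  pre_sat <- grids$ctni[grids$ctni <= cfg$sat_onset_ctni_cl]
  expect_true(all(diff(forward_signal(pre_sat, "ctni", "cl", cfg)) > 0))
})

test_that("large-replicate noise converges to the de-biased dispersion, and
           triplicate sample CVs to the configured CV", {
  cfg <- vfa_config()
  withr::local_seed(7)
  x <- forward_signal(rep(1000, 10000), "ckmb", "color", cfg, noise = TRUE)
  emp_cv <- 100 * sd(x) / mean(x)
  # the configured 3.0% is the expected *triplicate* sample CV; the underlying
  # dispersion is larger by 1/c4(3)
  c4 <- sqrt(2 / 2) * gamma(1.5) / gamma(1)
  target <- 3.0 / c4
  se <- target / sqrt(2 * (10000 - 1))  # SE of a CV estimate
  expect_lt(abs(emp_cv - target), 3 * se)

  trip_cv <- withr::with_seed(8, purrr::map_dbl(1:4000, function(i) {
    compute_cv(forward_signal(rep(1000, 3), "ckmb", "color", cfg, noise = TRUE))
  }))
  expect_lt(abs(mean(trip_cv) - 3.0), 3 * sd(trip_cv) / sqrt(4000))
})

test_that("simulated cartridges are deterministic under a fixed seed", {
  cfg <- tiny_config()
  coh <- sample_cohort(cfg, seed = 5)
  a <- simulate_signals(coh, cfg, seed = 6)
  b <- simulate_signals(coh, cfg, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, simulate_signals(coh, cfg, seed = 7)))
  # 16 spots x 2 modalities per cartridge
  expect_equal(nrow(a), nrow(coh) * 32L)
})

test_that("rendered membranes honour channel assignment and blank contract", {
  cfg <- vfa_config(n_patients = 1, pixel_noise_sd = 0.002)
  sm <- spot_map()
  coh <- sample_cohort(cfg, seed = 9)
  coh$conc_ctni <- 0; coh$conc_ckmb <- 0; coh$conc_ntprobnp <- 0
  pair <- render_membrane_pair(coh[1, ], sm, "color", cfg, seed = 10)
  rois <- dplyr::filter(sm, condition %in% c("ctni", "ckmb", "ntprobnp", "neg"))
  ints <- measure_intensities(pair$bg, pair$assay,
                              dplyr::mutate(rois, center_x = center_x,
                                            center_y = center_y,
                                            radius = 0.7 * radius_px),
                              "color")
  # all-blank test spots: post-assay ROI means near background
  expect_true(all(abs(ints$s - ints$b) < cfg$bg_level * cfg$blank_mean +
                    4 * cfg$pixel_noise_sd))

  # colorimetric contrast confined to green, CL contrast to blue
  coh2 <- sample_cohort(cfg, seed = 11)
  coh2$conc_ctni <- 1e4
  pc <- render_membrane_pair(coh2[1, ], sm, "color", cfg, seed = 12)
  pl <- render_membrane_pair(coh2[1, ], sm, "cl", cfg, seed = 13)
  ctni_roi <- dplyr::filter(sm, condition == "ctni")[1, ]
  px <- function(img, ch) {
    img[round(ctni_roi$center_y) + 1, round(ctni_roi$center_x) + 1, ch]
  }
  expect_lt(px(pc$assay, 2), cfg$bg_level - 0.05)   # green darkened
  expect_gt(px(pc$assay, 3), cfg$bg_level - 0.05)   # blue untouched
  expect_lt(px(pl$assay, 3), cfg$bg_level - 0.05)   # blue darkened in CL
  expect_gt(px(pl$assay, 2), cfg$bg_level - 0.05)
})

test_that("rendering fails when the image cannot contain the layout", {
  cfg <- vfa_config(image_size = 100)
  coh <- sample_cohort(vfa_config(n_patients = 1), seed = 1)
  expect_error(render_membrane_pair(coh[1, ], spot_map(), "color", cfg),
               "too small")
})
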