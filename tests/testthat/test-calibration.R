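test_that("power fit recovers exact power-law parameters on any grid", {
  grids <- list(10^seq(2, 5, length.out = 8),
                c(2, 5, 17, 300, 9000),
                10^seq(-1, 6, length.out = 12))
  for (g in grids) {
    pts <- data.frame(conc = g, signal = 2e-4 * g^0.6901)
    fit <- fit_power(pts)
    expect_equal(fit$k, 0.6901, tolerance = 1e-6)
    expect_equal(fit$a, 2e-4, tolerance = 1e-6)
    expect_gt(fit$r.squared, 1 - 1e-12)
  }
})

test_that("power fit edge cases: two points interpolate, constants give k = 0", {
  two <- fit_power(data.frame(conc = c(10, 1000), signal = c(0.01, 0.1)))
  expect_equal(two$r.squared, 1)
  expect_equal(predict_calibration(two, 10), 0.01, tolerance = 1e-12)
  expect_equal(predict_calibration(two, 1000), 0.1, tolerance = 1e-12)

  const <- fit_power(data.frame(conc = c(1, 10, 100), signal = rep(0.05, 3)))
  expect_equal(const$k, 0)
  expect_equal(const$a, 0.05)

  expect_error(fit_power(data.frame(conc = 1, signal = 1)), "at least 2")
  expect_error(fit_power(data.frame(conc = c(0, 1), signal = c(1, 1))), "> 0")
})

test_that("4-PL fit recovers its own parameters and flags degeneracy", {
  x <- 10^seq(0, 5, length.out = 12)
  truth <- list(A = 0.01, B = 1.2, C = 500, D = 0.9)
  y <- truth$D + (truth$A - truth$D) / (1 + (x / truth$C)^truth$B)
  fit <- fit_4pl(data.frame(conc = x, signal = y))
  for (p in names(truth)) {
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-4)
  }
  expect_error(fit_4pl(data.frame(conc = x, signal = rep(0.5, 12))),
               "degenerate")
  expect_error(fit_4pl(data.frame(conc = x[1:4], signal = y[1:4])),
               "at least 5")
})

test_that("4-PL is at least as flexible as the power law on the same points", {
  # noisy power data over a narrow range
  x <- 10^seq(2, 3, length.out = 8)
  y <- withr::with_seed(81, 2e-4 * x^0.69 * exp(rnorm(8, 0, 0.05)))
  pts <- data.frame(conc = x, signal = y)
  pw <- fit_power(pts)
  pl <- fit_4pl(pts)
  expect_gte(pl$r.squared, pw$r.squared.linear - 1e-6)
})

test_that("inversion is the exact inverse on the valid range", {
  pw <- fit_power(data.frame(conc = 10^(0:5), signal = 0.01 * (10^(0:5))^0.5))
  expect_equal(invert_calibration(pw, 0.01 * 123^0.5), 123, tolerance = 1e-9)
  sig <- withr::with_seed(82, runif(50, 0.001, 0.9))
  expect_equal(predict_calibration(pw, invert_calibration(pw, sig)), sig,
               tolerance = 1e-9)

  x <- 10^seq(0, 5, length.out = 12)
  y <- 0.9 + (0.01 - 0.9) / (1 + (x / 500)^1.2)
  pl <- fit_4pl(data.frame(conc = x, signal = y))
  expect_equal(invert_calibration(pl, (pl$A + pl$D) / 2), pl$C,
               tolerance = 1e-6)
  sig <- withr::with_seed(83, runif(50, pl$A + 0.01, pl$D - 0.01))
  expect_equal(predict_calibration(pl, invert_calibration(pl, sig)), sig,
               tolerance = 1e-9)
  expect_error(invert_calibration(pl, pl$D + 0.01), "out of invertible range")
  expect_error(invert_calibration(pw, -0.1), "out of invertible range")
})

test_that("limits of blank and detection follow their definitions", {
  pw <- fit_power(data.frame(conc = 10^(0:4), signal = 0.01 * (10^(0:4))^0.5))
  # zero-variance blanks and replicates: LoD = LoB = invert(mean blank)
  lim0 <- compute_limits(rep(0.011, 3), rep(0.02, 3), pw)
  expect_equal(lim0$lob, (0.011 / 0.01)^2)
  expect_equal(lim0$lod, lim0$lob)

  blanks <- c(0.010, 0.012, 0.011)
  lim <- compute_limits(blanks, rep(0.02, 3), pw)
  expect_equal(lim$lob, ((0.011 + 1.645 * sd(blanks)) / 0.01)^2)
  expect_equal(lim$lod, lim$lob)  # zero-variance low replicates

  lows <- c(0.019, 0.020, 0.021)
  lim2 <- compute_limits(blanks, lows, pw)
  expect_equal(lim2$lod,
               lim2$lob + 1.645 * sd(invert_calibration(pw, lows)))
  expect_gte(lim2$lod, lim2$lob)
  # LoD strictly increases with replicate spread
  lows_wide <- c(0.017, 0.020, 0.023)
  expect_gt(compute_limits(blanks, lows_wide, pw)$lod, lim2$lod)
  expect_error(compute_limits(blanks[1:2], lows, pw), "at least 3")
})

test_that("synthetic CK-MB detection limit sits below the clinical cut-off", {
  cfg <- vfa_config()
  pts <- data.frame(conc = cfg$calibration_grid$ckmb,
                    signal = forward_signal(cfg$calibration_grid$ckmb,
                                            "ckmb", "color", cfg))
  pw <- fit_power(pts)
  withr::local_seed(84)
  blanks <- forward_signal(rep(0, 10), "ckmb", "color", cfg, noise = TRUE)
  lowest <- min(cfg$calibration_grid$ckmb)
  lows <- forward_signal(rep(lowest, 10), "ckmb", "color", cfg, noise = TRUE)
  lim <- compute_limits(blanks, lows, pw)
  expect_lt(lim$lod, 5000)
})

test_that("coefficient of variation matches hand arithmetic and is scale invariant", {
  expect_equal(compute_cv(c(10, 10, 10)), 0)
  expect_equal(compute_cv(c(9, 11)), 100 * sqrt(2) / 10, tolerance = 1e-12)
  expect_equal(compute_cv(c(9, 11)), 14.14, tolerance = 1e-3)
  x <- withr::with_seed(85, runif(20, 1, 2))
  expect_equal(compute_cv(7 * x), compute_cv(x), tolerance = 1e-12)
  expect_error(compute_cv(5), "at least 2")
  expect_error(compute_cv(c(-1, 1)), "zero mean")
})

test_that("generator triplicates reproduce the configured replicate CV", {
  cfg <- vfa_config()
  cvs <- withr::with_seed(86, purrr::map_dbl(1:1000, function(i) {
    compute_cv(forward_signal(rep(2000, 3), "ckmb", "color", cfg, noise = TRUE))
  }))
  expect_equal(mean(cvs), 3.0, tolerance = 0.1)
})

test_that("tidy and glance expose calibration fits in broom shape", {
  pts <- data.frame(conc = 10^(1:6), signal = 2e-4 * (10^(1:6))^0.6901)
  pw <- fit_power(pts)
  td <- tidy(pw)
  expect_equal(td$term, c("a", "k"))
  expect_equal(td$estimate[2], 0.6901, tolerance = 1e-6)
  gl <- glance(pw)
  expect_true(all(c("r.squared", "n") %in% names(gl)))
  expect_equal(gl$n, 6L)
})
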