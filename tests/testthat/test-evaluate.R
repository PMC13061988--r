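test_that("classification report computes accuracy and a consistent confusion", {
  labels <- c("<500", ">=500")
  pred <- rep(labels, c(10, 10))
  truth <- pred
  rep0 <- classification_report(pred, truth, labels)
  expect_equal(rep0$accuracy, 1)
  conf <- rep0$confusion
  expect_equal(conf$`<500`[conf$truth == "<500"], 10)
  expect_equal(conf$`>=500`[conf$truth == "<500"], 0)

  truth2 <- truth
  truth2[1] <- ">=500"
  rep1 <- classification_report(pred, truth2, labels)
  expect_equal(rep1$accuracy, 19 / 20)
  # row sums equal per-class truth counts
  sums <- rowSums(as.matrix(rep1$confusion[, -1]))
  expect_equal(unname(sums), as.vector(table(factor(truth2, labels))))
  # permutation invariance
  perm <- withr::with_seed(1, sample(20))
  expect_equal(classification_report(pred[perm], truth2[perm], labels)$accuracy,
               rep1$accuracy)
  expect_error(classification_report(c("a"), c("<500"), labels), "class set")
})

test_that("correlation report has the affine and null properties", {
  y <- withr::with_seed(2, runif(50, 1, 100))
  expect_equal(correlation_report(y, y), 1)
  expect_equal(correlation_report(3 * y + 7, y), 1)
  null_r <- withr::with_seed(3, correlation_report(rnorm(1000), rnorm(1000)))
  expect_lt(abs(null_r), 0.1)
  expect_error(correlation_report(y[1:2], y[1:2]), "at least 3")
  expect_error(correlation_report(rep(1, 5), y[1:5]), "zero variance")
  # log option changes the scale it is computed on
  x <- 10^runif(30, 0, 4)
  expect_equal(correlation_report(x, x, log10 = TRUE), 1)
})

test_that("duplicate CV averages per-patient CVs and skips singletons", {
  df <- tibble::tibble(
    patient_id = c("a", "a", "b", "b", "c"),
    conc = c(90, 110, 50, 50, 10)
  )
  out <- duplicate_cv(df)
  expect_equal(out$per_patient$cv[out$per_patient$patient_id == "a"],
               100 * sqrt(2) * 10 / 100, tolerance = 1e-9)
  expect_equal(out$per_patient$cv[out$per_patient$patient_id == "b"], 0)
  expect_equal(out$n_skipped, 1L)
  expect_equal(out$mean_cv, mean(c(100 * sqrt(200) / 100, 0)))
  ident <- duplicate_cv(tibble::tibble(patient_id = c("x", "x"), conc = c(5, 5)))
  expect_equal(ident$mean_cv, 0)
})

test_that("duplicate CVs of simulated cohorts track the noise-implied level", {
  cfg <- vfa_config(n_patients = 150)
  coh <- sample_cohort(cfg, seed = 121)
  fv <- simulate_features(coh, cfg, seed = 122)
  # duplicate CV of the raw CK-MB colorimetric feature across cartridges:
  # replicate noise averaged over 3 spots plus the per-cartridge matrix factor
  keep <- !fv$cens_ckmb & fv$conc_ckmb > 500
  dup <- fv[keep, ] |>
    dplyr::group_by(patient_id) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(cv = compute_cv(X_ckmb_color))
  c4_2 <- sqrt(2 / pi)  # E[SD]/sigma for n = 2
  c4_3 <- sqrt(pi) / 2
  rel <- sqrt((cfg$replicate_cv[["ckmb"]] / 100 / c4_3)^2 / 3 +
                (cfg$matrix_cv / 100)^2)
  expected <- 100 * rel * c4_2
  se <- sd(dup$cv) / sqrt(nrow(dup))
  expect_lt(abs(mean(dup$cv) - expected), 4 * se + 0.15 * expected)
})

test_that("power-fit baseline inverts designated signals and respects range", {
  cfg <- vfa_config()
  grid <- cfg$calibration_grid$ckmb
  mdl <- fit_power(data.frame(conc = grid,
                              signal = forward_signal(grid, "ckmb", "color", cfg)))
  x0 <- 3000
  fv <- one_fv()
  fv$X_ckmb_color <- forward_signal(x0, "ckmb", "color", cfg)
  expect_equal(powerfit_baseline(fv, mdl, "ckmb"), x0, tolerance = 1e-6)

  # saturated cTnI CL signal against a model fit below the saturation onset
  pre <- cfg$calibration_grid$ctni[cfg$calibration_grid$ctni <= cfg$sat_onset_ctni_cl]
  mcl <- fit_power(data.frame(conc = pre,
                              signal = forward_signal(pre, "ctni", "cl", cfg)))
  fv$X_ctni_cl <- cfg$sat_plateau_ctni_cl + 0.02   # beyond anything fitted
  expect_error(powerfit_baseline(fv, mcl, "ctni"), "out of")
  expect_true(is.na(powerfit_baseline(fv, mcl, "ctni", on_out_of_range = "na")))
})

test_that("cascade evaluation partitions statuses and counts consistently", {
  cfg <- vfa_config(n_patients = 35)
  fv <- simulate_features(sample_cohort(cfg, seed = 131), cfg, seed = 132)
  casc <- train_cascade(fv, seed = 133, spec_overrides = list(epochs = 300L))
  preds <- predict_cascade(casc, fv)
  rep_ <- evaluate_cascade(preds, fv)
  expect_equal(nrow(rep_), 3L)
  expect_true(all(rep_$n_quantified + rep_$n_negative + rep_$n_undetermined ==
                    rep_$n))
  expect_true(all(rep_$accuracy >= 0 & rep_$accuracy <= 1))
  expect_true(all(is.na(rep_$pearson_r) | abs(rep_$pearson_r) <= 1))
  conf <- rep_$confusion[[1]]
  expect_equal(sum(as.matrix(conf[, -1])), rep_$n[1])
})
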