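# shared fixtures: everything is generated in code at test time

tiny_config <- function(...) vfa_config(n_patients = 4, ...)

# a quick training recipe for structural NN tests (not the study conditions)
fast_overrides <- list(epochs = 150L)

# separable two-class feature frame over the CK-MB colorimetric feature set
separable_classes <- function(n = 40, gap = 1, seed = 1) {
  withr::with_seed(seed, data.frame(
    X_ctni_color = c(rnorm(n / 2, -gap, 0.2), rnorm(n / 2, gap, 0.2)),
    X_ntprobnp_color = rnorm(n),
    X_ckmb_color = rnorm(n),
    X_pos_color = rnorm(n),
    X_neg_color = rnorm(n)
  ))
}

# feature frame whose target depends only on one planted column
planted_signal_data <- function(n = 60, seed = 2) {
  withr::with_seed(seed, {
    x <- runif(n, -1, 1)
    list(
      features = data.frame(
        X_ctni_color = rnorm(n), X_ntprobnp_color = rnorm(n),
        X_ckmb_color = x, X_pos_color = rnorm(n), X_neg_color = rnorm(n)
      ),
      classes = ifelse(x > 0, 2L, 1L),
      conc = 500 + 1000 * (x + 1)
    )
  })
}

# a single neutral feature vector
one_fv <- function() {
  fv <- tibble::as_tibble(setNames(as.list(rep(0.1, 10)),
                                   dualvfa:::feature_cols()))
  fv$sample_id <- "S1"
  fv
}

# a stub cascade whose predictions we control exactly, for rule tests
stub_cascade <- function(class_idx, quant_value) {
  fake_clf <- structure(list(fixed_class = class_idx), class = "fake_clf")
  fake_q <- structure(list(value = quant_value), class = "fake_q")
  models <- list(
    ctni_class = fake_clf, ctni_lt40 = fake_q, ctni_40_1000 = fake_q,
    ctni_gt1000 = fake_q,
    ckmb_class = fake_clf, ckmb_ge500 = fake_q,
    ntprobnp_class = fake_clf, ntprobnp_ge125 = fake_q
  )
  structure(list(models = models, seed = 1L), class = "vfa_cascade")
}

# predict methods for the stubs (register with registerS3method in each test)
predict.fake_clf <- function(object, newdata, type = "class", ...) {
  rep(object$fixed_class, nrow(newdata))
}
predict.fake_q <- function(object, newdata, ...) {
  rep(object$value, nrow(newdata))
}
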