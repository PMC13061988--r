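# ---- reference implementations of the training losses ----
# (the compiled training core re-implements these in C++; these R versions
#  define the contract and are cross-checked against it in the tests)

#' Row-wise softmax
#'
#' Converts logits to class probabilities, `exp(z) / sum(exp(z))` per row,
#' with max-subtraction for numerical stability. Rows sum to 1; adding a
#' constant to all logits of a row leaves the output unchanged.
#'
#' @param logits A numeric matrix (samples x classes) or vector (one sample).
#' @return A matrix of probabilities with the same shape.
#' @examples
#' softmax(c(log(1), log(3))) # 0.25, 0.75
#' @export
softmax <- function(logits) {
  if (is.vector(logits)) logits <- matrix(logits, nrow = 1)
  if (any(!is.finite(logits))) abort("logits must be finite")
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Categorical cross-entropy loss
#'
#' Mean over the batch of the negative log predicted probability of the true
#' class: `-(1/N) sum_n sum_c y[n,c] log y'[n,c]` with one-hot `y`.
#' Probabilities at the true class that are `<= 0` are clipped at 1e-12 with
#' a warning.
#'
#' @param y One-hot true-label matrix (samples x classes).
#' @param y_prob Predicted probability matrix on the simplex, same shape.
#' @return Scalar loss, `>= 0`, zero iff the prediction is exactly one-hot
#'   on the true class.
#' @export
cce_loss <- function(y, y_prob) {
  y <- as.matrix(y); y_prob <- as.matrix(y_prob)
  stopifnot(identical(dim(y), dim(y_prob)))
  if (any(abs(rowSums(y) - 1) > 1e-8) || any(y != 0 & y != 1)) {
    abort("y rows must be one-hot")
  }
  if (any(abs(rowSums(y_prob) - 1) > 1e-6) || any(y_prob < 0)) {
    abort("y_prob rows must lie on the probability simplex")
  }
  p_true <- rowSums(y * y_prob)
  if (any(p_true <= 0)) {
    warn("zero predicted probability at the true class; clipping at 1e-12")
    p_true <- pmax(p_true, 1e-12)
  }
  -mean(log(p_true))
}

#' Mean squared error loss
#'
#' `(1/N) sum (y - y')^2`.
#'
#' @param y,y_prime Numeric vectors of targets and predictions.
#' @return Scalar loss.
#' @export
mse_loss <- function(y, y_prime) {
  stopifnot(length(y) == length(y_prime))
  mean((y - y_prime)^2)
}

#' Root-mean-square-log-error loss (per-sample form)
#'
#' The default evaluates the per-sample form used by the assay's
#' quantification pipeline,
#' `(1/N) sum sqrt((log(y+1) - log(y'+1))^2)`, in which the root cancels the
#' square sample by sample, giving the mean absolute log1p error (natural
#' log). This is not the conventional batch-level RMSLE; set
#' `conventional = TRUE` for `sqrt((1/N) sum (log1p y - log1p y')^2)`.
#'
#' @param y,y_prime Numeric vectors, both `> -1`.
#' @param conventional Use the batch-level square root instead.
#' @return Scalar loss; symmetric in `y` and `y_prime`.
#' @export
rmsle_loss <- function(y, y_prime, conventional = FALSE) {
  stopifnot(length(y) == length(y_prime))
  if (any(y <= -1) || any(y_prime <= -1)) {
    abort("rmsle requires y and y' > -1")
  }
  d <- log1p(y) - log1p(y_prime)
  if (conventional) sqrt(mean(d^2)) else mean(abs(d))
}
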