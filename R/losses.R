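#' Training losses
#'
#' The three candidate training objectives, evaluated over a batch of
#' `m` prediction/target pairs (for image training, the pixels of the
#' reconstruction):
#'
#' * **Mean square error**: `sum((y - yhat)^2) / m`.
#' * **Cross-entropy** (returned negated so the value is non-negative
#'   and minimized at perfect prediction):
#'   `-(1/m) * sum(y * log(h) + (1 - y) * log(1 - h))`, where pixel
#'   intensities in `[0, 1]` play the role of Bernoulli targets and
#'   predictions are clamped to `[eps, 1 - eps]`.
#' * **Log-likelihood**: `-sum(y * log(h))`, again with clamped
#'   predictions.
#'
#' The clamp (`eps = 1e-7`) is part of the function definition: its
#' derivative is zero where the clamp is active, which keeps analytic
#' gradients consistent with finite differences.
#'
#' @param predictions Numeric vector of model outputs.
#' @param targets Numeric vector of the same length.
#' @return Scalar loss value.
#' @name losses
NULL

#' @rdname losses
#' @export
mse_loss <- function(predictions, targets) {
  check_batch(predictions, targets)
  mean((targets - predictions)^2)
}

#' @rdname losses
#' @export
cross_entropy_loss <- function(predictions, targets) {
  check_batch(predictions, targets)
  if (any(targets < 0 | targets > 1))
    stop("cross-entropy targets must lie in [0, 1]", call. = FALSE)
  h <- clamp01(predictions)
  -mean(targets * log(h) + (1 - targets) * log(1 - h))
}

#' @rdname losses
#' @export
log_likelihood_loss <- function(predictions, targets) {
  check_batch(predictions, targets)
  h <- clamp01(predictions)
  -sum(targets * log(h))
}

#' Gradient of a training loss with respect to the predictions
#'
#' Elementwise `d loss / d yhat_i` for the loss selected by
#' `loss_kind`; this is the signal backpropagation seeds the network
#' with.  Where the `(0, 1)` clamp of the probabilistic losses is
#' active, the derivative is exactly zero (the clamp is flat there).
#'
#' @inheritParams losses
#' @param loss_kind One of `"mse"`, `"cross_entropy"`,
#'   `"log_likelihood"`.
#' @return Numeric vector of per-prediction derivatives.
#' @export
loss_gradient <- function(predictions, targets, loss_kind = "mse") {
  check_batch(predictions, targets)
  m <- length(predictions)
  switch(match_loss(loss_kind),
    mse = 2 * (predictions - targets) / m,
    cross_entropy = {
      h <- clamp01(predictions)
      g <- (-targets / h + (1 - targets) / (1 - h)) / m
      g * clamp_active(predictions)
    },
    log_likelihood = {
      h <- clamp01(predictions)
      (-targets / h) * clamp_active(predictions)
    })
}

#' @rdname loss_gradient
#' @export
loss_value <- function(predictions, targets, loss_kind = "mse") {
  switch(match_loss(loss_kind),
    mse = mse_loss(predictions, targets),
    cross_entropy = cross_entropy_loss(predictions, targets),
    log_likelihood = log_likelihood_loss(predictions, targets))
}

# --- internal ---------------------------------------------------------------

LOSS_KINDS <- c("mse", "cross_entropy", "log_likelihood")
CLAMP_EPS <- 1e-7

match_loss <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% LOSS_KINDS)
    stop("unknown loss kind; use one of: ",
         paste(LOSS_KINDS, collapse = ", "), call. = FALSE)
  kind
}

check_batch <- function(predictions, targets) {
  if (length(predictions) == 0L)
    stop("empty batch", call. = FALSE)
  if (length(predictions) != length(targets))
    stop("predictions and targets must have equal length", call. = FALSE)
  invisible(TRUE)
}

clamp01 <- function(x) pmin(pmax(x, CLAMP_EPS), 1 - CLAMP_EPS)

# 1 where the clamp is inactive, 0 where it saturates
clamp_active <- function(x) as.numeric(x > CLAMP_EPS & x < 1 - CLAMP_EPS)
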