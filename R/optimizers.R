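#' Optimizer configuration
#'
#' Hyperparameters for the four supported update rules.  `alpha` is the
#' learning rate; `beta` is the decay of the single accumulator used by
#' momentum and RMSProp; `beta1`/`beta2` are Adam's first-/second-moment
#' decays and `theta` its stability constant (added to the square root
#' of the corrected second moment in the denominator).
#'
#' Defaults: `beta1 = 0.9`, `beta2 = 0.999`, `theta = 1e-8`;
#' `alpha = 1e-3` for Adam/RMSProp and `1e-2` for plain and momentum
#' gradient descent (the learning rate is the one knob with no single
#' sensible default across rules).
#'
#' @param kind One of `"sgd"`, `"momentum"`, `"rmsprop"`, `"adam"`.
#' @param alpha Learning rate (> 0).
#' @param beta Momentum/RMSProp decay in `[0, 1)`.
#' @param beta1,beta2 Adam moment decays in `[0, 1)`.
#' @param theta Stability constant (> 0).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(kind = c("adam", "sgd", "momentum", "rmsprop"),
                             alpha = NULL, beta = 0.9,
                             beta1 = 0.9, beta2 = 0.999, theta = 1e-8) {
  kind <- match.arg(kind)
  if (is.null(alpha))
    alpha <- if (kind %in% c("adam", "rmsprop")) 1e-3 else 1e-2
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (beta < 0 || beta >= 1 || beta1 < 0 || beta1 >= 1 ||
      beta2 < 0 || beta2 >= 1)
    stop("decay parameters must lie in [0, 1)", call. = FALSE)
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  structure(list(kind = kind, alpha = alpha, beta = beta,
                 beta1 = beta1, beta2 = beta2, theta = theta),
            class = "optimizer_config")
}

#' Optimizer state
#'
#' Per-parameter first- and second-moment accumulators plus the global
#' iteration counter `t`.  A fresh state has `t = 0` and all
#' accumulators zero; `t` counts completed steps and drives Adam's bias
#' correction `1 - beta^t`.
#'
#' @param params Named list of numeric arrays (see [model_params()]);
#'   accumulators are allocated with matching shapes.
#' @return An object of class `optimizer_state`.
#' @export
optimizer_state <- function(params) {
  zeros <- lapply(params, function(p) { p[] <- 0; p })
  structure(list(t = 0L, first = zeros, second = zeros),
            class = "optimizer_state")
}

#' Reset an optimizer state
#'
#' Returns the state to `t = 0` with zeroed accumulators; idempotent,
#' and equal to a freshly constructed state.
#'
#' @param state An [optimizer_state()].
#' @return The reset `optimizer_state`.
#' @export
optimizer_reset <- function(state) {
  stopifnot(inherits(state, "optimizer_state"))
  state$t <- 0L
  state$first <- lapply(state$first, function(p) { p[] <- 0; p })
  state$second <- lapply(state$second, function(p) { p[] <- 0; p })
  state
}

#' One optimizer step over a parameter collection
#'
#' Applies the selected update rule uniformly to every array in
#' `params` given congruent `grads`:
#'
#' * `sgd`: `p <- p - alpha * g`
#' * `momentum`: `D <- beta * D + (1 - beta) * g`; `p <- p - alpha * D`
#' * `rmsprop`: `E <- beta * E + (1 - beta) * g^2`;
#'   `p <- p - alpha * g / (sqrt(E) + theta)`
#' * `adam`: `D <- beta1 * D + (1 - beta1) * g`;
#'   `E <- beta2 * E + (1 - beta2) * g^2`; with bias correction
#'   `Dhat = D / (1 - beta1^t)`, `Ehat = E / (1 - beta2^t)` at step
#'   `t`, `p <- p - alpha * Dhat / (sqrt(Ehat) + theta)`
#'
#' The iteration counter is global per training run (one `t` for all
#' parameters) and is incremented before the Adam bias correction, so
#' the first step uses `t = 1`.
#'
#' @param params Named list of numeric arrays.
#' @param grads Named list of numeric arrays, shapes congruent with
#'   `params`.
#' @param state An [optimizer_state()] allocated for `params`.
#' @param config An [optimizer_config()].
#' @return List with updated `params` and `state`.
#' @examples
#' cfg <- optimizer_config("adam", alpha = 0.1)
#' st <- optimizer_state(list(w = 1))
#' optimizer_step(list(w = 1), list(w = 1), st, cfg)$params$w  # ~0.9
#' @export
optimizer_step <- function(params, grads, state, config) {
  stopifnot(inherits(state, "optimizer_state"),
            inherits(config, "optimizer_config"))
  if (!identical(names(params), names(grads)))
    stop("params and grads must have matching names", call. = FALSE)
  for (nm in names(params))
    if (length(params[[nm]]) != length(grads[[nm]]))
      stop("gradient shape mismatch for '", nm, "'", call. = FALSE)

  state$t <- state$t + 1L
  a <- config$alpha
  for (nm in names(params)) {
    g <- grads[[nm]]
    p <- params[[nm]]
    upd <- switch(config$kind,
      sgd = a * g,
      momentum = {
        state$first[[nm]] <- config$beta * state$first[[nm]] +
          (1 - config$beta) * g
        a * state$first[[nm]]
      },
      rmsprop = {
        state$second[[nm]] <- config$beta * state$second[[nm]] +
          (1 - config$beta) * g * g
        a * g / (sqrt(state$second[[nm]]) + config$theta)
      },
      adam = {
        state$first[[nm]] <- config$beta1 * state$first[[nm]] +
          (1 - config$beta1) * g
        state$second[[nm]] <- config$beta2 * state$second[[nm]] +
          (1 - config$beta2) * g * g
        d_hat <- state$first[[nm]] / (1 - config$beta1^state$t)
        e_hat <- state$second[[nm]] / (1 - config$beta2^state$t)
        a * d_hat / (sqrt(e_hat) + config$theta)
      })
    params[[nm]] <- p - upd
  }
  list(params = params, state = state)
}
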