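#' Construct a convolution layer
#'
#' A 2-D convolution layer in the CNN convention (cross-correlation, no
#' kernel flip) with zero "same" padding, per-output-channel bias and an
#' optional ReLU activation.  Kernels must have odd side lengths so the
#' padding is symmetric and output spatial size equals input size.
#'
#' @param weights 4-D numeric array indexed
#'   `(kernel_row, kernel_col, in_channel, out_channel)`.
#' @param bias Numeric vector, one entry per output channel.
#' @param apply_relu Logical; apply the rectifier `g(x) = max(x, 0)`
#'   after the affine map.
#' @return An object of class `conv_layer`.
#' @export
conv_layer <- function(weights, bias, apply_relu = TRUE) {
  if (length(dim(weights)) != 4L)
    stop("weights must be a 4-D array (k, k, in, out)", call. = FALSE)
  d <- dim(weights)
  if (d[1] %% 2L == 0L || d[2] %% 2L == 0L)
    stop("kernel dimensions must be odd for symmetric same-padding",
         call. = FALSE)
  if (length(bias) != d[4])
    stop("bias length must equal the number of output channels",
         call. = FALSE)
  structure(list(weights = weights, bias = as.numeric(bias),
                 apply_relu = isTRUE(apply_relu)),
            class = "conv_layer")
}

#' Assemble a super-resolution CNN
#'
#' Validates channel compatibility between consecutive layers and that
#' the final layer emits a single channel with no activation (the
#' reconstruction stage must be able to produce the full intensity
#' range, including values a rectifier would clip).
#'
#' @param layers List of [conv_layer()] objects.
#' @return An object of class `srcnn_model`.
#' @seealso [init_srcnn()], [sr_forward()], [sr_backward()]
#' @export
srcnn_model <- function(layers) {
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "conv_layer")))
  for (i in seq_along(layers)[-1]) {
    if (dim(layers[[i]]$weights)[3] != dim(layers[[i - 1]]$weights)[4])
      stop(sprintf("layer %d expects %d input channels but layer %d emits %d",
                   i, dim(layers[[i]]$weights)[3], i - 1,
                   dim(layers[[i - 1]]$weights)[4]), call. = FALSE)
  }
  last <- layers[[length(layers)]]
  if (dim(last$weights)[4] != 1L)
    stop("final layer must output a single channel", call. = FALSE)
  if (last$apply_relu)
    stop("final layer must not apply ReLU", call. = FALSE)
  structure(list(layers = layers), class = "srcnn_model")
}

#' Initialize a three-stage super-resolution CNN
#'
#' Builds the canonical feature-extraction / nonlinear-mapping /
#' reconstruction stack.  Weights are zero-mean Gaussian with variance
#' `2 / fan_in` (the rectifier-appropriate scaling), biases zero, all
#' seeded.  Defaults follow the classical 9-1-5 configuration with 64
#' and 32 hidden channels; both kernel sizes and channel widths are
#' fully configurable, including deeper stacks (one hidden mapping
#' layer per extra entry).
#'
#' @param kernels Integer vector of odd kernel sizes, one per layer.
#' @param channels Integer vector of hidden channel counts
#'   (`length(kernels) - 1` entries; the final layer always emits 1).
#' @param seed Integer seed for the weight draw.
#' @return An `srcnn_model`.
#' @examples
#' m <- init_srcnn(kernels = c(5, 1, 3), channels = c(8, 4), seed = 1)
#' @export
init_srcnn <- function(kernels = c(9L, 1L, 5L), channels = c(64L, 32L),
                       seed = 1L) {
  kernels <- as.integer(kernels); channels <- as.integer(channels)
  if (length(channels) != length(kernels) - 1L)
    stop("need length(kernels) - 1 hidden channel counts", call. = FALSE)
  rng <- local_rng(seed)
  n_in <- c(1L, channels)
  n_out <- c(channels, 1L)
  layers <- vector("list", length(kernels))
  for (i in seq_along(kernels)) {
    k <- kernels[i]
    fan_in <- k * k * n_in[i]
    w <- array(rng$rnorm(k * k * n_in[i] * n_out[i], 0, sqrt(2 / fan_in)),
               dim = c(k, k, n_in[i], n_out[i]))
    layers[[i]] <- conv_layer(w, bias = rep(0, n_out[i]),
                              apply_relu = i < length(kernels))
  }
  srcnn_model(layers)
}

#' Rectified linear unit
#'
#' `g(x) = x` for `x >= 0`, else 0, applied elementwise.  The
#' subgradient at 0 used in backpropagation is 0.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape.
#' @export
relu <- function(x) pmax(x, 0)

#' Forward pass through one convolution layer
#'
#' Cross-correlates the input with every kernel under zero "same"
#' padding, adds the per-channel bias, and applies ReLU if the layer
#' requests it.  Spatial dimensions are preserved.
#'
#' @param x Numeric matrix (single channel) or `H x W x C` array; the
#'   channel count must match the layer's kernels.
#' @param layer A [conv_layer()].
#' @return `H x W x C_out` array (drop to a matrix with `[, , 1]`).
#' @export
conv_forward <- function(x, layer) {
  stopifnot(inherits(layer, "conv_layer"))
  x <- as_stack(x)
  d <- dim(layer$weights)
  if (dim(x)[3] != d[3])
    stop(sprintf("input has %d channels, layer expects %d",
                 dim(x)[3], d[3]), call. = FALSE)
  h <- dim(x)[1]; w <- dim(x)[2]
  M <- im2col(x, d[1], d[2])
  W <- matrix(layer$weights, nrow = d[1] * d[2] * d[3], ncol = d[4])
  out <- M %*% W
  out <- sweep(out, 2, layer$bias, `+`)
  if (layer$apply_relu) out <- pmax(out, 0)
  array(out, dim = c(h, w, d[4]))
}

#' Forward pass through the whole network
#'
#' Chains [conv_forward()] over all layers and returns the
#' reconstructed image at the input's spatial size.  Deterministic: no
#' hidden randomness.
#'
#' @param model An [srcnn_model()].
#' @param lr Numeric matrix: the (pre-upsampled, normalized)
#'   low-resolution input.
#' @return Numeric matrix, the reconstructed image.
#' @export
sr_forward <- function(model, lr) {
  stopifnot(inherits(model, "srcnn_model"))
  x <- as_stack(lr)
  for (layer in model$layers) x <- conv_forward(x, layer)
  x[, , 1]
}

#' @rdname sr_forward
#' @param object,... S3 `predict` method arguments (`lr` passed through).
#' @export
predict.srcnn_model <- function(object, lr, ...) sr_forward(object, lr)

#' Backpropagation: gradients of the training loss
#'
#' Runs the forward pass, evaluates the selected loss between the
#' reconstruction and the target, and propagates the loss derivative
#' back through every layer, producing analytic gradients for all
#' weights and biases.  The pixel collection of the output is treated
#' as the loss's sample (`m = H * W`).
#'
#' @param model An [srcnn_model()].
#' @param lr Input image (matrix), same size as `target`.
#' @param target Ground-truth high-resolution image (matrix).
#' @param loss_kind One of `"mse"`, `"cross_entropy"`,
#'   `"log_likelihood"`.
#' @return A `gradient_set`: list with `loss` (scalar) and `layers`, a
#'   list of `list(d_weights, d_bias)` mirroring the model's shapes.
#' @export
sr_backward <- function(model, lr, target, loss_kind = "mse") {
  stopifnot(inherits(model, "srcnn_model"), is.matrix(lr), is.matrix(target))
  if (!identical(dim(lr), dim(target)))
    stop("input and target dimensions differ", call. = FALSE)
  L <- length(model$layers)
  h <- nrow(lr); w <- ncol(lr)

  # forward with caches: inputs and pre-activation sign masks per layer
  x <- as_stack(lr)
  inputs <- vector("list", L)   # input stack to each layer
  cols <- vector("list", L)     # im2col of that input
  masks <- vector("list", L)    # post-ReLU positive mask (NULL if no relu)
  for (i in seq_len(L)) {
    layer <- model$layers[[i]]
    d <- dim(layer$weights)
    inputs[[i]] <- x
    M <- im2col(x, d[1], d[2])
    cols[[i]] <- M
    out <- sweep(M %*% matrix(layer$weights, d[1] * d[2] * d[3], d[4]),
                 2, layer$bias, `+`)
    if (layer$apply_relu) {
      masks[[i]] <- out > 0
      out <- pmax(out, 0)
    }
    x <- array(out, dim = c(dim(x)[1], dim(x)[2], d[4]))
  }
  yhat <- as.numeric(x[, , 1])
  y <- as.numeric(target)
  loss <- loss_value(yhat, y, loss_kind)
  dyhat <- loss_gradient(yhat, y, loss_kind)

  grads <- vector("list", L)
  delta <- matrix(dyhat, ncol = 1L)        # (H*W) x C_out matrix form
  for (i in rev(seq_len(L))) {
    layer <- model$layers[[i]]
    d <- dim(layer$weights)
    if (layer$apply_relu) delta <- delta * masks[[i]]
    d_bias <- colSums(delta)
    dW <- crossprod(cols[[i]], delta)      # (k*k*Cin) x Cout
    grads[[i]] <- list(d_weights = array(dW, dim = d), d_bias = d_bias)
    if (i > 1L) {
      W <- matrix(layer$weights, d[1] * d[2] * d[3], d[4])
      G <- delta %*% t(W)                  # (H*W) x (k*k*Cin)
      dx <- col2im_add(G, h, w, d[1], d[2], d[3])
      delta <- matrix(dx, nrow = h * w, ncol = d[3])
    }
  }
  structure(list(loss = loss, layers = grads), class = "gradient_set")
}

#' Flatten model parameters / gradients to a named list of arrays
#'
#' Optimizers operate on flat lists; these helpers convert between an
#' `srcnn_model` and the list representation (`w1, b1, w2, b2, ...`).
#'
#' @param model An `srcnn_model`.
#' @return Named list of numeric arrays.
#' @export
model_params <- function(model) {
  out <- list()
  for (i in seq_along(model$layers)) {
    out[[paste0("w", i)]] <- model$layers[[i]]$weights
    out[[paste0("b", i)]] <- model$layers[[i]]$bias
  }
  out
}

#' @rdname model_params
#' @param params Named list as returned by [model_params()].
#' @export
set_model_params <- function(model, params) {
  for (i in seq_along(model$layers)) {
    model$layers[[i]]$weights <- params[[paste0("w", i)]]
    model$layers[[i]]$bias <- params[[paste0("b", i)]]
  }
  model
}

#' @rdname model_params
#' @param grads A `gradient_set` from [sr_backward()].
#' @export
gradient_list <- function(grads) {
  out <- list()
  for (i in seq_along(grads$layers)) {
    out[[paste0("w", i)]] <- grads$layers[[i]]$d_weights
    out[[paste0("b", i)]] <- grads$layers[[i]]$d_bias
  }
  out
}

#' @export
print.srcnn_model <- function(x, ...) {
  cat("Super-resolution CNN with", length(x$layers), "layers\n")
  for (i in seq_along(x$layers)) {
    d <- dim(x$layers[[i]]$weights)
    cat(sprintf("  layer %d: %dx%d kernel, %d -> %d channels%s\n",
                i, d[1], d[2], d[3], d[4],
                if (x$layers[[i]]$apply_relu) ", ReLU" else ""))
  }
  invisible(x)
}

# --- internal ---------------------------------------------------------------

as_stack <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L))
  else if (length(dim(x)) == 3L) x
  else stop("expected a matrix or an H x W x C array", call. = FALSE)
}

# im2col for zero "same" padding: rows index output pixels
# (column-major over H x W), columns index (k_row, k_col, channel)
# in array column-major order, matching matrix(weights, k*k*C, C_out).
im2col <- function(x, kh, kw) {
  h <- dim(x)[1]; w <- dim(x)[2]; ch <- dim(x)[3]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  pad <- array(0, dim = c(h + 2L * ph, w + 2L * pw, ch))
  pad[ph + seq_len(h), pw + seq_len(w), ] <- x
  M <- matrix(0, h * w, kh * kw * ch)
  col <- 0L
  for (c in seq_len(ch)) for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    col <- col + 1L
    M[, col] <- pad[ki + seq_len(h) - 1L, kj + seq_len(w) - 1L, c]
  }
  M
}

# adjoint of im2col: scatter-add column blocks back onto the input grid
col2im_add <- function(G, h, w, kh, kw, ch) {
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  pad <- array(0, dim = c(h + 2L * ph, w + 2L * pw, ch))
  col <- 0L
  for (c in seq_len(ch)) for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    col <- col + 1L
    rows <- ki + seq_len(h) - 1L; colsw <- kj + seq_len(w) - 1L
    pad[rows, colsw, c] <- pad[rows, colsw, c] + matrix(G[, col], h, w)
  }
  pad[ph + seq_len(h), pw + seq_len(w), , drop = FALSE]
}
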