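test_that("relu follows its two branches and the boundary", {
  expect_equal(relu(2.5), 2.5)
  expect_equal(relu(-3), 0)
  expect_equal(relu(0), 0)
  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
})

test_that("1x1 identity kernel passes the input through", {
  layer <- conv_layer(array(1, c(1, 1, 1, 1)), bias = 0, apply_relu = FALSE)
  x <- matrix(runif(36), 6)
  expect_equal(conv_forward(x, layer)[, , 1], x)
})

test_that("zero weights give a constant bias map", {
  layer <- conv_layer(array(0, c(3, 3, 1, 1)), bias = 0.7,
                      apply_relu = FALSE)
  out <- conv_forward(matrix(runif(16), 4), layer)
  expect_equal(out[, , 1], matrix(0.7, 4, 4))
})

test_that("conv_forward matches the nested-loop oracle", {
  set.seed(31)
  # single kernel on a small input
  w <- array(rnorm(9), c(3, 3, 1, 1))
  layer <- conv_layer(w, bias = 0.1, apply_relu = FALSE)
  x <- matrix(runif(16), 4)
  expect_equal(conv_forward(x, layer), conv_oracle(x, w, 0.1, FALSE),
               tolerance = 1e-12)
  # multi-channel in and out, with ReLU
  w2 <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b2 <- rnorm(3)
  x2 <- array(runif(5 * 7 * 2), c(5, 7, 2))
  layer2 <- conv_layer(w2, b2, apply_relu = TRUE)
  expect_equal(conv_forward(x2, layer2), conv_oracle(x2, w2, b2, TRUE),
               tolerance = 1e-12)
})

test_that("channel mismatch and even kernels are rejected", {
  layer <- conv_layer(array(0, c(3, 3, 2, 1)), bias = 0, apply_relu = FALSE)
  expect_error(conv_forward(matrix(0, 4, 4), layer), "channels")
  expect_error(conv_layer(array(0, c(2, 2, 1, 1)), 0), "odd")
  expect_error(conv_layer(array(0, c(3, 3, 1, 2)), 0), "bias length")
})

test_that("model validation enforces compatibility and final-layer contract", {
  l1 <- conv_layer(array(0, c(3, 3, 1, 2)), rep(0, 2))
  l_bad <- conv_layer(array(0, c(3, 3, 3, 1)), 0, apply_relu = FALSE)
  expect_error(srcnn_model(list(l1, l_bad)), "channels")
  l_relu_end <- conv_layer(array(0, c(3, 3, 2, 1)), 0, apply_relu = TRUE)
  expect_error(srcnn_model(list(l1, l_relu_end)), "ReLU")
  l_multi_out <- conv_layer(array(0, c(3, 3, 2, 2)), rep(0, 2),
                            apply_relu = FALSE)
  expect_error(srcnn_model(list(l1, l_multi_out)), "single channel")
})

test_that("forward pass equals composed brute-force convolutions", {
  m <- small_model(seed = 12)
  x <- matrix(runif(16 * 16), 16)
  got <- sr_forward(m, x)
  ref <- x
  for (l in m$layers)
    ref <- conv_oracle(ref, l$weights, l$bias, l$apply_relu)
  expect_equal(got, ref[, , 1], tolerance = 1e-10)
})

test_that("forward is deterministic and preserves size", {
  m <- small_model(seed = 8)
  x <- matrix(runif(100), 10)
  expect_identical(sr_forward(m, x), sr_forward(m, x))
  expect_equal(dim(sr_forward(m, x)), dim(x))
})

test_that("interior translation equivariance holds for bias-free layers", {
  set.seed(55)
  w <- array(rnorm(9), c(3, 3, 1, 1))
  layer <- conv_layer(w, bias = 0, apply_relu = FALSE)
  x <- matrix(runif(144), 12)
  xs <- rbind(x[-1, ], 0)               # shift up by one row
  y <- conv_forward(x, layer)[, , 1]
  ys <- conv_forward(xs, layer)[, , 1]
  # away from the padding border, shifting input shifts output
  expect_equal(ys[3:9, 3:10], y[4:10, 3:10], tolerance = 1e-12)
})

test_that("gradients vanish at the loss minimum and scale linearly", {
  m <- small_model(seed = 3)
  x <- matrix(runif(64), 8)
  target <- sr_forward(m, x)
  gs <- sr_backward(m, x, target, "mse")
  expect_equal(gs$loss, 0)
  for (l in gs$layers) {
    expect_equal(max(abs(l$d_weights)), 0)
    expect_equal(max(abs(l$d_bias)), 0)
  }
  # linearity: scaling residuals by c scales mse gradients by c
  hr <- matrix(runif(64), 8)
  g1 <- gradient_list(sr_backward(m, x, hr, "mse"))
  hr2 <- target + 2 * (hr - target)   # doubles every residual
  g2 <- gradient_list(sr_backward(m, x, hr2, "mse"))
  for (nm in names(g1)) expect_equal(g2[[nm]], 2 * g1[[nm]],
                                     tolerance = 1e-9)
})

test_that("analytic gradients match finite differences for all losses", {
  set.seed(99)
  lr <- matrix(runif(64, 0.05, 0.95), 8)
  hr <- matrix(runif(64, 0.05, 0.95), 8)
  for (loss in c("mse", "cross_entropy", "log_likelihood")) {
    m <- small_model(seed = 17)
    expect_lt(fd_gradcheck(m, lr, hr, loss), 1e-4)
  }
})

test_that("unsupported loss kinds raise a configuration error", {
  m <- small_model(seed = 1)
  x <- matrix(runif(16), 4)
  expect_error(sr_backward(m, x, x, "hinge"), "unknown loss")
})

test_that("parameter list round-trips through set_model_params", {
  m <- small_model(seed = 5)
  p <- model_params(m)
  p$w1 <- p$w1 * 2
  m2 <- set_model_params(m, p)
  expect_equal(m2$layers[[1]]$weights, m$layers[[1]]$weights * 2)
  expect_equal(model_params(m2), p)
})

test_that("checkpoints round-trip through JSON", {
  m <- small_model(seed = 23)
  path <- file.path(tempdir(), "ckpt.json")
  save_checkpoint(m, path, meta = list(seed = 23))
  m2 <- load_checkpoint(path)
  x <- matrix(runif(64), 8)
  expect_equal(sr_forward(m2, x), sr_forward(m, x), tolerance = 1e-12)
})
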