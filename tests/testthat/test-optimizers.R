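test_that("zero gradient leaves parameters unchanged for every rule", {
  p <- list(w = matrix(1:4 / 4, 2), b = c(0.5, -0.5))
  g <- list(w = matrix(0, 2, 2), b = c(0, 0))
  for (kind in c("sgd", "momentum", "rmsprop", "adam")) {
    st <- optimizer_state(p)
    out <- optimizer_step(p, g, st, optimizer_config(kind))
    expect_equal(out$params, p)
  }
})

test_that("adam first step reproduces the hand-evaluated example", {
  # w = 1, g = 1, alpha = 0.1: D = 0.1, E = 0.001, Dhat = 1, Ehat = 1,
  # w' = 1 - 0.1 / (1 + 1e-8)
  st <- optimizer_state(list(w = 1))
  out <- optimizer_step(list(w = 1), list(w = 1), st,
                        optimizer_config("adam", alpha = 0.1))
  expect_equal(out$params$w, 1 - 0.1 / (1 + 1e-8), tolerance = 1e-12)
  expect_equal(out$state$t, 1L)
  expect_equal(out$state$first$w, 0.1)
  expect_equal(out$state$second$w, 0.001)
})

test_that("adam's first-step magnitude is ~alpha regardless of gradient scale", {
  for (gmag in c(1e-4, 1, 1e4)) {
    st <- optimizer_state(list(w = 0))
    out <- optimizer_step(list(w = 0), list(w = gmag), st,
                          optimizer_config("adam", alpha = 0.05))
    expect_equal(abs(out$params$w), 0.05, tolerance = 1e-3)
  }
})

test_that("momentum with beta = 0 equals plain gradient descent exactly", {
  set.seed(6)
  grads <- rnorm(50)
  p_sgd <- list(w = 2); p_mom <- list(w = 2)
  st_s <- optimizer_state(p_sgd); st_m <- optimizer_state(p_mom)
  cfg_s <- optimizer_config("sgd", alpha = 0.03)
  cfg_m <- optimizer_config("momentum", alpha = 0.03, beta = 0)
  for (g in grads) {
    o_s <- optimizer_step(p_sgd, list(w = g), st_s, cfg_s)
    o_m <- optimizer_step(p_mom, list(w = g), st_m, cfg_m)
    p_sgd <- o_s$params; st_s <- o_s$state
    p_mom <- o_m$params; st_m <- o_m$state
    expect_identical(p_sgd$w, p_mom$w)
  }
})

test_that("vectorized steps match the scalar oracle over 100-step sequences", {
  set.seed(7)
  grads <- rnorm(100, sd = 2)
  for (kind in c("sgd", "momentum", "rmsprop", "adam")) {
    cfg <- optimizer_config(kind, alpha = 0.01, beta = 0.9)
    p <- list(w = 1.5); st <- optimizer_state(p)
    traj <- numeric(100)
    for (t in 1:100) {
      out <- optimizer_step(p, list(w = grads[t]), st, cfg)
      p <- out$params; st <- out$state
      traj[t] <- p$w
    }
    ref <- scalar_opt_oracle(kind, 1.5, grads, alpha = 0.01, beta = 0.9)
    expect_equal(traj, ref, tolerance = 1e-12)
  }
})

test_that("a single small step decreases f(w) = w^2 for all rules", {
  for (kind in c("sgd", "momentum", "rmsprop", "adam")) {
    p <- list(w = 1)
    st <- optimizer_state(p)
    out <- optimizer_step(p, list(w = 2 * p$w), st,
                          optimizer_config(kind, alpha = 1e-3))
    expect_lt(out$params$w^2, 1)
  }
})

test_that("adam and rmsprop converge faster than sgd on a 2-D quadratic", {
  # f(w) = 0.5 * (10 * w1^2 + 0.1 * w2^2): badly conditioned on purpose
  run <- function(kind, alpha) {
    p <- list(w = c(1, 1)); st <- optimizer_state(p)
    cfg <- optimizer_config(kind, alpha = alpha)
    for (t in 1:2000) {
      g <- list(w = c(10 * p$w[1], 0.1 * p$w[2]))
      out <- optimizer_step(p, g, st, cfg)
      p <- out$params; st <- out$state
      f <- 0.5 * (10 * p$w[1]^2 + 0.1 * p$w[2]^2)
      if (f < 1e-3) return(t)
    }
    Inf
  }
  it_sgd <- run("sgd", 0.01)
  it_adam <- run("adam", 0.05)
  it_rms <- run("rmsprop", 0.05)
  expect_lt(it_adam, it_sgd)
  expect_lt(it_rms, it_sgd)
})

test_that("reset returns a state equal to a fresh one and is idempotent", {
  p <- list(w = matrix(1, 2, 2))
  st <- optimizer_state(p)
  cfg <- optimizer_config("adam")
  st2 <- optimizer_step(p, list(w = matrix(1, 2, 2)), st, cfg)$state
  expect_gt(st2$t, 0)
  r1 <- optimizer_reset(st2)
  expect_equal(r1, optimizer_state(p))
  expect_equal(optimizer_reset(r1), r1)
  # reset then zero-gradient step leaves parameters unchanged
  out <- optimizer_step(p, list(w = matrix(0, 2, 2)), r1, cfg)
  expect_equal(out$params, p)
})

test_that("shape mismatches and unknown kinds are rejected", {
  p <- list(w = c(1, 2))
  st <- optimizer_state(p)
  expect_error(optimizer_step(p, list(w = 1), st, optimizer_config("sgd")),
               "shape mismatch")
  expect_error(optimizer_step(p, list(v = c(1, 2)), st,
                              optimizer_config("sgd")), "matching names")
  expect_error(optimizer_config("adagrad"), "arg")
})

test_that("second-moment accumulators stay non-negative", {
  set.seed(8)
  p <- list(w = rnorm(5)); st <- optimizer_state(p)
  cfg <- optimizer_config("adam", alpha = 0.01)
  for (t in 1:50) {
    out <- optimizer_step(p, list(w = rnorm(5)), st, cfg)
    p <- out$params; st <- out$state
    expect_true(all(st$second$w >= 0))
  }
})
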