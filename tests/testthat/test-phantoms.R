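test_that("phantom generation is seeded-deterministic and respects range", {
  spec <- phantom_spec(height = 48, width = 48, n_structures = 5, seed = 42)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(dim(a), c(48L, 48L))
  # a different seed gives a different image
  c <- generate_phantom(phantom_spec(height = 48, width = 48,
                                     n_structures = 5, seed = 43))
  expect_false(identical(a, c))
})

test_that("single sharp structure at fixed intensity paints exactly that value", {
  spec <- phantom_spec(height = 32, width = 32, n_structures = 1,
                       intensity_range = c(0.5, 0.5), blur_sigma = 0,
                       annulus_fraction = 0, seed = 5)
  img <- generate_phantom(spec)
  nz <- img[img != 0]
  expect_gt(length(nz), 0)
  expect_true(all(nz == 0.5))
})

test_that("gaussian noise has the stated first moment away from clipping", {
  base <- list(height = 96, width = 96, n_structures = 3,
               intensity_range = c(0.4, 0.6), blur_sigma = 2,
               annulus_fraction = 0, seed = 9)
  clean <- generate_phantom(do.call(phantom_spec, base))
  noisy <- generate_phantom(do.call(phantom_spec,
    c(base, list(noise_model = "gaussian", noise_sigma = 0.05))))
  # restrict to pixels where the +-0.05 noise cannot hit the [0,1] clamp
  sel <- clean > 0.25 & clean < 0.75
  n <- sum(sel)
  expect_gt(n, 500)
  expect_lt(abs(mean(noisy[sel] - clean[sel])), 3 * 0.05 / sqrt(n))
})

test_that("rician noise is non-negative and biases dark pixels upward", {
  spec <- phantom_spec(height = 64, width = 64, n_structures = 2,
                       noise_model = "rician", noise_sigma = 0.05, seed = 3)
  img <- generate_phantom(spec)
  expect_true(all(img >= 0))
  clean <- generate_phantom(phantom_spec(height = 64, width = 64,
                                         n_structures = 2, seed = 3))
  # on the zero background the Rician magnitude floor is strictly positive
  expect_gt(mean(img[clean == 0]), 0)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(height = 8), "at least 16")
  expect_error(phantom_spec(n_structures = 0), "n_structures")
  expect_error(phantom_spec(intensity_range = c(0.9, 0.1)), "intensity_range")
  expect_error(phantom_spec(intensity_range = c(0, 1.5)), "intensity_range")
  expect_error(phantom_spec(blur_sigma = -1), "non-negative")
})

test_that("identity degradation returns the input untouched", {
  img <- generate_phantom(phantom_spec(height = 32, width = 32, seed = 1))
  out <- degrade(img, degradation_spec(1L, pre_blur_sigma = 0))
  expect_identical(out, img)
})

test_that("constant images are fixed points of degradation", {
  img <- matrix(0.37, 32, 32)
  out <- degrade(img, degradation_spec(2L))
  expect_lt(max(abs(out - 0.37)), 1e-6)
})

test_that("decimation+reupsampling matches an independent spline routine", {
  img <- outer(1:8, 1:8, function(i, j) (i + j) %% 2) * 0.8  # checkerboard
  out <- degrade(img, degradation_spec(2L, pre_blur_sigma = 0))
  lr <- img[seq(1, 8, 2), seq(1, 8, 2)]
  # reference: separable cubic splines written out directly
  xs <- (seq_len(4) - 1) * 2 + 1
  mid <- sapply(seq_len(4), function(j) spline(xs, lr[, j], xout = 1:8)$y)
  ref <- t(sapply(seq_len(8), function(i) spline(xs, mid[i, ], xout = 1:8)$y))
  ref <- pmin(pmax(ref, 0), max(img))
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("non-divisible dimensions raise a shape error", {
  img <- matrix(0.5, 33, 32)
  expect_error(degrade(img, degradation_spec(2L)), "divisible")
})

test_that("degradation preserves the valid intensity range", {
  img <- generate_phantom(phantom_spec(height = 48, width = 48, seed = 8))
  for (s in c(2L, 4L)) {
    out <- degrade(img, degradation_spec(s))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("PSNR of the degraded image decreases with pre-blur width", {
  img <- generate_phantom(phantom_spec(height = 64, width = 64, seed = 21))
  ps <- vapply(c(0.5, 1, 2), function(sig)
    psnr(img, degrade(img, degradation_spec(2L, pre_blur_sigma = sig))), 0)
  expect_true(all(is.finite(ps)))
  expect_true(all(diff(ps) < 0))
})
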