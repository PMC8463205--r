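#' Specification of a synthetic MRI-like phantom
#'
#' Describes a piecewise-smooth 2-D phantom built from overlapping
#' elliptical plateaus (with optional annular, crescent-like structures)
#' on a dark background.  Phantoms stand in for high-resolution
#' acquisitions so that every stage of the super-resolution pipeline can
#' be exercised without external image data.  All randomness (structure
#' placement, intensities, noise) flows from the single `seed` field, so
#' a spec fully determines its image.
#'
#' @param height,width Image dimensions in pixels (>= 16).
#' @param n_structures Number of elliptical/annular components (>= 1).
#' @param intensity_range Length-2 numeric, `0 <= low <= high <= 1`;
#'   structure plateau intensities are drawn uniformly from this range.
#' @param blur_sigma Standard deviation (pixels) of the final Gaussian
#'   smoothing that softens structure edges; 0 disables smoothing.
#' @param noise_model One of `"none"`, `"gaussian"`, `"rician"`.
#'   Magnitude MRI noise is Rician; Gaussian is provided for generic
#'   testing.  Default `"none"`.
#' @param noise_sigma Noise standard deviation in intensity units (>= 0).
#' @param annulus_fraction Fraction of structures rendered as annuli
#'   (elliptical ring with a hollow core), mimicking crescent-shaped
#'   menisci; deterministic given the seed.
#' @param seed Integer seed controlling all randomness.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(height = 256L, width = 256L, n_structures = 8L,
                         intensity_range = c(0.25, 0.95), blur_sigma = 1,
                         noise_model = c("none", "gaussian", "rician"),
                         noise_sigma = 0, annulus_fraction = 0.3,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  height <- as.integer(height); width <- as.integer(width)
  n_structures <- as.integer(n_structures)
  if (height < 16L || width < 16L)
    stop("phantom dimensions must be at least 16x16", call. = FALSE)
  if (n_structures < 1L)
    stop("n_structures must be >= 1", call. = FALSE)
  if (length(intensity_range) != 2L ||
      intensity_range[1] > intensity_range[2] ||
      intensity_range[1] < 0 || intensity_range[2] > 1)
    stop("intensity_range must be (low, high) with 0 <= low <= high <= 1",
         call. = FALSE)
  if (blur_sigma < 0 || noise_sigma < 0)
    stop("blur_sigma and noise_sigma must be non-negative", call. = FALSE)
  structure(
    list(height = height, width = width, n_structures = n_structures,
         intensity_range = as.numeric(intensity_range),
         blur_sigma = blur_sigma, noise_model = noise_model,
         noise_sigma = noise_sigma, annulus_fraction = annulus_fraction,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Generate a synthetic high-resolution phantom image
#'
#' Renders the phantom described by a [phantom_spec()]: ellipses (and
#' annuli) with constant intensity plateaus are combined with a pixelwise
#' maximum, optionally Gaussian-smoothed, and optionally corrupted with
#' Gaussian or Rician noise.  Output intensities are clipped to `[0, 1]`.
#' Calling twice with the same spec returns bit-identical images.
#'
#' @param spec A [phantom_spec()].
#' @return A numeric `height x width` matrix with values in `[0, 1]`.
#' @examples
#' img <- generate_phantom(phantom_spec(height = 64, width = 64, seed = 7))
#' range(img)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rng <- local_rng(spec$seed)
  h <- spec$height; w <- spec$width
  img <- matrix(0, h, w)
  yy <- matrix(seq_len(h), h, w)           # row coordinate
  xx <- matrix(rep(seq_len(w), each = h), h, w)
  lo <- spec$intensity_range[1]; hi <- spec$intensity_range[2]
  for (k in seq_len(spec$n_structures)) {
    cy <- rng$runif(1, 0.2 * h, 0.8 * h)
    cx <- rng$runif(1, 0.2 * w, 0.8 * w)
    a  <- rng$runif(1, 0.08, 0.35) * h / 2   # semi-axes
    b  <- rng$runif(1, 0.08, 0.35) * w / 2
    th <- rng$runif(1, 0, pi)
    val <- rng$runif(1, lo, hi)
    annulus <- rng$runif(1) < spec$annulus_fraction
    dy <- yy - cy; dx <- xx - cx
    u <- ( cos(th) * dy + sin(th) * dx) / a
    v <- (-sin(th) * dy + cos(th) * dx) / b
    r2 <- u * u + v * v
    mask <- r2 <= 1
    if (annulus) mask <- mask & r2 >= rng$runif(1, 0.25, 0.6)
    img[mask] <- pmax(img[mask], val)
  }
  if (spec$blur_sigma > 0) img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$noise_model == "gaussian" && spec$noise_sigma > 0) {
    img <- img + rng$rnorm(h * w, 0, spec$noise_sigma)
  } else if (spec$noise_model == "rician" && spec$noise_sigma > 0) {
    n1 <- rng$rnorm(h * w, 0, spec$noise_sigma)
    n2 <- rng$rnorm(h * w, 0, spec$noise_sigma)
    img <- sqrt((img + n1)^2 + n2^2)
  }
  pmin(pmax(img, 0), 1)
}

#' Specification of the low-resolution degradation model
#'
#' The acquisition-to-observation model used to manufacture
#' low-resolution inputs from high-resolution images: Gaussian pre-blur
#' (anti-aliasing), decimation by an integer factor, and spline
#' re-upsampling back onto the original grid.  The re-upsampling step
#' means the degraded image has the same size as the ground truth, so
#' the network maps like to like (pre-upsampling convention).
#'
#' @param scale_factor Integer >= 1; must divide both image dimensions.
#' @param pre_blur_sigma Gaussian blur applied before decimation, in
#'   pixels; default `scale_factor / 2`, the usual anti-alias width.
#' @param interp_order Order of the interpolation used to re-upsample:
#'   0 (nearest), 1 (linear) or 3 (cubic spline, default).
#' @return An object of class `degradation_spec`.
#' @seealso [degrade()], [upscale_baseline()]
#' @export
degradation_spec <- function(scale_factor = 2L,
                             pre_blur_sigma = scale_factor / 2,
                             interp_order = 3L) {
  scale_factor <- as.integer(scale_factor)
  if (scale_factor < 1L) stop("scale_factor must be >= 1", call. = FALSE)
  if (pre_blur_sigma < 0) stop("pre_blur_sigma must be >= 0", call. = FALSE)
  if (!interp_order %in% c(0L, 1L, 3L))
    stop("interp_order must be 0, 1 or 3", call. = FALSE)
  structure(list(scale_factor = scale_factor,
                 pre_blur_sigma = pre_blur_sigma,
                 interp_order = as.integer(interp_order)),
            class = "degradation_spec")
}

#' Degrade a high-resolution image to its low-resolution observation
#'
#' Applies blur -> decimate -> re-upsample per a [degradation_spec()].
#' With `scale_factor = 1` and `pre_blur_sigma = 0` this is the
#' identity.  Output is clipped to the input's `[0, max]` range so
#' spline overshoot cannot leave the valid intensity range.
#'
#' @param hr Numeric matrix; both dimensions must be divisible by
#'   `spec$scale_factor`.
#' @param spec A [degradation_spec()].
#' @return Numeric matrix with the same dimensions as `hr`.
#' @export
degrade <- function(hr, spec) {
  stopifnot(is.matrix(hr), inherits(spec, "degradation_spec"))
  s <- spec$scale_factor
  if (nrow(hr) %% s != 0L || ncol(hr) %% s != 0L)
    stop("image dimensions must be divisible by scale_factor", call. = FALSE)
  out <- hr
  if (spec$pre_blur_sigma > 0) out <- gaussian_blur(out, spec$pre_blur_sigma)
  if (s > 1L) {
    lr <- out[seq(1L, nrow(out), by = s), seq(1L, ncol(out), by = s),
              drop = FALSE]
    out <- resample_to(lr, nrow(hr), ncol(hr), scale = s,
                       order = spec$interp_order)
  }
  top <- max(hr)
  pmin(pmax(out, min(0, min(hr))), max(top, 0))
}

#' Extract the native-resolution low-res image (decimated, not re-upsampled)
#'
#' Convenience for baselines that interpolate from the coarse grid:
#' blur + decimate without the re-upsampling step.
#'
#' @inheritParams degrade
#' @return Numeric matrix of size `dim(hr) / scale_factor`.
#' @export
decimate_native <- function(hr, spec) {
  stopifnot(is.matrix(hr), inherits(spec, "degradation_spec"))
  s <- spec$scale_factor
  if (nrow(hr) %% s != 0L || ncol(hr) %% s != 0L)
    stop("image dimensions must be divisible by scale_factor", call. = FALSE)
  out <- hr
  if (spec$pre_blur_sigma > 0) out <- gaussian_blur(out, spec$pre_blur_sigma)
  out[seq(1L, nrow(out), by = s), seq(1L, ncol(out), by = s), drop = FALSE]
}

# --- internal helpers ------------------------------------------------------

# Isolated RNG stream: returns closures drawing from a private .Random.seed
# so phantom generation never disturbs (or depends on) the global RNG state.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  draw <- function(fun) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(runif = draw(stats::runif), rnorm = draw(stats::rnorm),
       sample = draw(base::sample))
}

#' Gaussian blur with edge replication
#'
#' Separable Gaussian filter; borders are handled by replicating the
#' edge pixel, so constant images are exact fixed points.
#'
#' @param img Numeric matrix.
#' @param sigma Standard deviation in pixels (> 0).
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  ker <- exp(-x^2 / (2 * sigma^2))
  ker <- ker / sum(ker)
  blur1 <- function(m) {          # filter along rows (dim 1)
    n <- nrow(m)
    idx <- pmin(pmax(outer(seq_len(n), x, `+`), 1L), n)  # n x (2r+1)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(ker)) out <- out + ker[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(blur1(t(blur1(img))))
}

# Separable 1-D interpolation from a coarse grid back to a fine grid.
# Coarse sample i sits at fine coordinate (i - 1) * scale + 1.
resample_to <- function(lr, h, w, scale, order = 3L) {
  interp1 <- function(xs, ys, xout) {
    if (order == 3L) {
      if (length(ys) < 4L)
        stats::approx(xs, ys, xout = xout, rule = 2)$y
      else
        stats::spline(xs, ys, xout = xout, method = "fmm")$y
    } else if (order == 1L) {
      stats::approx(xs, ys, xout = xout, rule = 2)$y
    } else {
      ys[pmin(pmax(round((xout - 1) / scale) + 1, 1), length(ys))]
    }
  }
  xs_r <- (seq_len(nrow(lr)) - 1) * scale + 1
  xs_c <- (seq_len(ncol(lr)) - 1) * scale + 1
  mid <- apply(lr, 2, function(col) interp1(xs_r, col, seq_len(h)))
  mid <- matrix(mid, nrow = h)
  out <- t(apply(mid, 1, function(row) interp1(xs_c, row, seq_len(w))))
  matrix(out, nrow = h, ncol = w)
}
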