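#' Image-quality metric configuration
#'
#' Constants for PSNR and SSIM.  `L` is the peak signal value of the
#' PSNR ratio and `R` the pixel value range entering the SSIM stability
#' constants `c1 = (k1 * R)^2`, `c2 = (k2 * R)^2`, `c3 = c2 / 2` (`c3`
#' is maintained automatically).  Both default to 1 because pipeline
#' images are max-normalized; for raw 8-bit images use
#' `metric_config(L = 255, R = 255)`.  The component exponents default
#' to `alpha = beta = gamma = 1` and the stability fractions to
#' `k1 = 0.01`, `k2 = 0.03`.
#'
#' @param L Peak signal value for PSNR.
#' @param R Pixel value range for SSIM.
#' @param k1,k2 Stability fractions.
#' @param alpha,beta,gamma Exponents of the luminance, contrast and
#'   structure components.
#' @param window `"global"` (whole-image moments, the default) or
#'   `"sliding"` (uniform windows, mean SSIM over all positions).
#' @param window_size Side length of the sliding window in pixels.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(L = 1, R = 1, k1 = 0.01, k2 = 0.03,
                          alpha = 1, beta = 1, gamma = 1,
                          window = c("global", "sliding"),
                          window_size = 8L) {
  window <- match.arg(window)
  if (L <= 0 || R <= 0) stop("L and R must be > 0", call. = FALSE)
  if (k1 <= 0 || k2 <= 0) stop("k1 and k2 must be > 0", call. = FALSE)
  c2 <- (k2 * R)^2
  structure(list(L = L, R = R, k1 = k1, k2 = k2,
                 c1 = (k1 * R)^2, c2 = c2, c3 = c2 / 2,
                 alpha = alpha, beta = beta, gamma = gamma,
                 window = window, window_size = as.integer(window_size)),
            class = "metric_config")
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(L^2 / MSE)` in decibels, with
#' `MSE = mean((f - g)^2)` over all pixels.  Identical images have zero
#' MSE; the function then returns `Inf` (a distinguished sentinel,
#' never silently clipped).
#'
#' @param f Reference (ideal) image, numeric matrix.
#' @param g Image under evaluation, same dimensions.
#' @param config A [metric_config()].
#' @return PSNR in dB (possibly `Inf`).
#' @examples
#' f <- matrix(0.5, 8, 8)
#' psnr(f, f + 0.1)  # exactly 20 dB with L = 1
#' @export
psnr <- function(f, g, config = metric_config()) {
  stopifnot(is.matrix(f), is.matrix(g))
  if (!identical(dim(f), dim(g)))
    stop("image dimensions differ", call. = FALSE)
  mse <- mean((f - g)^2)
  if (mse == 0) return(Inf)
  10 * log10(config$L^2 / mse)
}

#' Structural similarity (SSIM)
#'
#' Single-scale SSIM as the product of luminance, contrast and
#' structure similarities:
#' `Lum = (2*mu_f*mu_g + c1) / (mu_f^2 + mu_g^2 + c1)`,
#' `Con = (2*sd_f*sd_g + c2) / (sd_f^2 + sd_g^2 + c2)`,
#' `Str = (cov_fg + c3) / (sd_f*sd_g + c3)`,
#' `SSIM = Lum^alpha * Con^beta * Str^gamma`.
#' Moments use the population convention (divide by N).  With
#' `window = "global"` (default) the statistics are whole-image
#' moments; with `"sliding"`, uniform `window_size`-square windows at
#' every position fully inside the image are evaluated and the means
#' over windows are reported.
#'
#' @inheritParams psnr
#' @return A `quality_report`: list with `ssim`, `luminance`,
#'   `contrast`, `structure`, and the moment statistics used.
#' @export
ssim <- function(f, g, config = metric_config()) {
  stopifnot(is.matrix(f), is.matrix(g))
  if (!identical(dim(f), dim(g)))
    stop("image dimensions differ", call. = FALSE)
  if (config$window == "global") {
    rep_ <- ssim_window(as.numeric(f), as.numeric(g), config)
  } else {
    ws <- config$window_size
    if (ws > nrow(f) || ws > ncol(f))
      stop("window_size exceeds image dimensions", call. = FALSE)
    acc <- c(ssim = 0, luminance = 0, contrast = 0, structure = 0)
    n <- 0L
    for (r in seq_len(nrow(f) - ws + 1L))
      for (cc in seq_len(ncol(f) - ws + 1L)) {
        wrep <- ssim_window(
          as.numeric(f[r:(r + ws - 1L), cc:(cc + ws - 1L)]),
          as.numeric(g[r:(r + ws - 1L), cc:(cc + ws - 1L)]), config)
        acc <- acc + c(wrep$ssim, wrep$luminance, wrep$contrast,
                       wrep$structure)
        n <- n + 1L
      }
    acc <- acc / n
    rep_ <- list(ssim = acc[["ssim"]], luminance = acc[["luminance"]],
                 contrast = acc[["contrast"]],
                 structure = acc[["structure"]],
                 mu_f = NA_real_, mu_g = NA_real_, sd_f = NA_real_,
                 sd_g = NA_real_, cov_fg = NA_real_)
  }
  structure(rep_, class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("SSIM %.6f (luminance %.6f, contrast %.6f, structure %.6f)\n",
              x$ssim, x$luminance, x$contrast, x$structure))
  invisible(x)
}

# single-window SSIM on flattened vectors (population moments)
ssim_window <- function(fv, gv, config) {
  n <- length(fv)
  mu_f <- mean(fv); mu_g <- mean(gv)
  var_f <- sum((fv - mu_f)^2) / n
  var_g <- sum((gv - mu_g)^2) / n
  sd_f <- sqrt(var_f); sd_g <- sqrt(var_g)
  cov_fg <- sum((fv - mu_f) * (gv - mu_g)) / n
  lum <- (2 * mu_f * mu_g + config$c1) / (mu_f^2 + mu_g^2 + config$c1)
  con <- (2 * sd_f * sd_g + config$c2) / (var_f + var_g + config$c2)
  str <- (cov_fg + config$c3) / (sd_f * sd_g + config$c3)
  list(ssim = lum^config$alpha * con^config$beta * str^config$gamma,
       luminance = lum, contrast = con, structure = str,
       mu_f = mu_f, mu_g = mu_g, sd_f = sd_f, sd_g = sd_g,
       cov_fg = cov_fg)
}

#' Batch quality evaluation
#'
#' Evaluates PSNR and SSIM for a collection of image pairs and returns
#' a tidy data frame (one row per pair), suitable for writing to CSV.
#'
#' @param pairs List of `list(hr = , recon = )` image pairs.
#' @param config A [metric_config()].
#' @param ids Optional identifiers (default sequence numbers).
#' @return Data frame with columns `id`, `psnr`, `ssim`, `luminance`,
#'   `contrast`, `structure`.
#' @export
evaluate_pairs <- function(pairs, config = metric_config(), ids = NULL) {
  if (is.null(ids)) ids <- seq_along(pairs)
  rows <- lapply(seq_along(pairs), function(i) {
    s <- ssim(pairs[[i]]$hr, pairs[[i]]$recon, config)
    data.frame(id = ids[i],
               psnr = psnr(pairs[[i]]$hr, pairs[[i]]$recon, config),
               ssim = s$ssim, luminance = s$luminance,
               contrast = s$contrast, structure = s$structure)
  })
  do.call(rbind, rows)
}
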