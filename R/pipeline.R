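#' Training configuration
#'
#' Everything that determines a training run: the loss, the optimizer,
#' the architecture, patching, and the master seed.  Two runs with
#' identical configurations and data produce identical models and
#' histories — all randomness (weight initialization, batch shuffling)
#' flows from `seed`.
#'
#' @param loss_kind `"mse"` (default), `"cross_entropy"` or
#'   `"log_likelihood"`.
#' @param optimizer An [optimizer_config()]; Adam by default.
#' @param epochs Passes over the training patches.
#' @param batch_size Patches per minibatch.
#' @param patch_size,stride Patch geometry (see [extract_patches()]).
#' @param kernels,channels Architecture (see [init_srcnn()]).
#' @param seed Master seed.
#' @param eval_every Evaluate validation PSNR every this many
#'   iterations (minibatches).
#' @return An object of class `training_config`.
#' @export
training_config <- function(loss_kind = "mse",
                            optimizer = optimizer_config("adam"),
                            epochs = 30L, batch_size = 16L,
                            patch_size = 32L, stride = 16L,
                            kernels = c(9L, 1L, 5L),
                            channels = c(64L, 32L),
                            seed = 1L, eval_every = 10L) {
  match_loss(loss_kind)
  stopifnot(inherits(optimizer, "optimizer_config"))
  if (epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(loss_kind = loss_kind, optimizer = optimizer,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 kernels = as.integer(kernels),
                 channels = as.integer(channels),
                 seed = as.integer(seed),
                 eval_every = as.integer(eval_every)),
            class = "training_config")
}

#' Generate a paired phantom dataset
#'
#' Draws `n` independent phantoms (seeds `seed, seed + 1, ...`),
#' degrades each with the given degradation model, and returns
#' high-/low-resolution pairs with the low-resolution image already
#' re-upsampled onto the target grid.
#'
#' @param n Number of images.
#' @param height,width Image dimensions.
#' @param degradation A [degradation_spec()].
#' @param seed Base seed; image `i` uses `seed + i - 1`.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return List of `n` pairs `list(hr = , lr = )`.
#' @export
phantom_dataset <- function(n, height = 64L, width = 64L,
                            degradation = degradation_spec(2L),
                            seed = 1L, ...) {
  lapply(seq_len(n), function(i) {
    hr <- generate_phantom(phantom_spec(height = height, width = width,
                                        seed = seed + i - 1L, ...))
    list(hr = hr, lr = degrade(hr, degradation))
  })
}

#' Build a training patch set from image pairs
#'
#' @param pairs List of `list(hr = , lr = )` pairs.
#' @param patch_size,stride Patch geometry.
#' @param augment Apply dihedral augmentation ([augment_patches()]).
#' @return A `patch_set` pooling all pairs.
#' @export
pairs_to_patches <- function(pairs, patch_size = 32L, stride = 16L,
                             augment = FALSE) {
  sets <- lapply(pairs, function(p)
    extract_patches(p$lr, p$hr, patch_size, stride))
  out <- combine_patch_sets(sets)
  if (augment) out <- augment_patches(out)
  out
}

#' Train the super-resolution network
#'
#' Minibatch training: shuffled passes over the patch set, analytic
#' backpropagation ([sr_backward()]) averaged over each batch, and a
#' parameter update per [optimizer_step()].  Training loss and mean
#' validation PSNR are logged every `eval_every` iterations (and at
#' iteration 0 and the final iteration).  A non-finite training loss
#' aborts with an error naming the iteration.
#'
#' @param config A [training_config()].
#' @param patches A `patch_set` of aligned low-/high-resolution
#'   patches.
#' @param val_pairs List of `list(hr = , lr = )` validation pairs
#'   (full images).
#' @return List with `model` (the trained `srcnn_model`) and `history`
#'   (data frame: `iteration`, `loss`, `val_psnr`).
#' @export
sr_train <- function(config, patches, val_pairs) {
  stopifnot(inherits(config, "training_config"),
            inherits(patches, "patch_set"))
  if (patches$n < 1L || length(val_pairs) < 1L)
    stop("training and validation sets must be non-empty", call. = FALSE)
  model <- init_srcnn(config$kernels, config$channels, seed = config$seed)
  mcfg <- metric_config()
  val_psnr <- function(m) {
    mean(vapply(val_pairs,
                function(p) psnr(p$hr, sr_forward(m, p$lr), mcfg), 0))
  }
  n_batches <- ceiling(patches$n / config$batch_size)
  total_iter <- config$epochs * n_batches
  if (total_iter == 0L)
    return(list(model = model,
                history = data.frame(iteration = integer(),
                                     loss = numeric(),
                                     val_psnr = numeric())))
  rng <- local_rng(config$seed + 1L)
  params <- model_params(model)
  state <- optimizer_state(params)
  hist_it <- 0L; hist_loss <- NA_real_; hist_psnr <- val_psnr(model)
  iter <- 0L
  loss_acc <- 0; loss_n <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- rng$sample(patches$n)
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * config$batch_size + 1L):
                   min(b * config$batch_size, patches$n)]
      g_sum <- NULL; loss_b <- 0
      for (k in idx) {
        gs <- sr_backward(model, patches$lr[, , k], patches$hr[, , k],
                          config$loss_kind)
        gl <- gradient_list(gs)
        loss_b <- loss_b + gs$loss
        g_sum <- if (is.null(g_sum)) gl
                 else mapply(`+`, g_sum, gl, SIMPLIFY = FALSE)
      }
      nb <- length(idx)
      g_sum <- lapply(g_sum, `/`, nb)
      loss_b <- loss_b / nb
      iter <- iter + 1L
      if (!is.finite(loss_b))
        stop("training diverged (non-finite loss) at iteration ", iter,
             call. = FALSE)
      stepped <- optimizer_step(params, g_sum, state, config$optimizer)
      params <- stepped$params; state <- stepped$state
      model <- set_model_params(model, params)
      loss_acc <- loss_acc + loss_b; loss_n <- loss_n + 1L
      if (iter %% config$eval_every == 0L || iter == total_iter) {
        hist_it <- c(hist_it, iter)
        hist_loss <- c(hist_loss, loss_acc / loss_n)
        hist_psnr <- c(hist_psnr, val_psnr(model))
        loss_acc <- 0; loss_n <- 0L
      }
    }
  }
  list(model = model,
       history = data.frame(iteration = hist_it, loss = hist_loss,
                            val_psnr = hist_psnr))
}

#' Cubic-spline interpolation baseline
#'
#' Upsamples a native-resolution low-res image onto the target grid by
#' separable spline interpolation — the classical non-learned
#' comparator for super-resolution.
#'
#' @param lr_native Numeric matrix at the coarse resolution.
#' @param scale_factor Integer upsampling factor (>= 1).
#' @param interp_order 3 for cubic splines (default), 1 linear,
#'   0 nearest.
#' @return Numeric matrix of size `dim(lr_native) * scale_factor`.
#' @export
upscale_baseline <- function(lr_native, scale_factor, interp_order = 3L) {
  stopifnot(is.matrix(lr_native), scale_factor >= 1L)
  if (scale_factor == 1L) return(lr_native)
  resample_to(lr_native, nrow(lr_native) * scale_factor,
              ncol(lr_native) * scale_factor, scale = scale_factor,
              order = as.integer(interp_order))
}

#' Compare reconstruction methods on a held-out set
#'
#' Evaluates PSNR and SSIM per image for the spline-interpolation
#' baseline (the stored `lr`, which is the spline-upsampled
#' observation) and the trained network's reconstruction, plus any
#' externally supplied reconstructions, and reports mean and standard
#' deviation of PSNR and mean SSIM per method.  The standard deviation
#' of a single-image set is reported as 0.
#'
#' @param model An `srcnn_model` (or `NULL` to skip the network).
#' @param test_pairs List of `list(hr = , lr = )` pairs.
#' @param config A [metric_config()].
#' @param extra Optional named list; each element is a list of
#'   reconstructed images aligned with `test_pairs`, added as an extra
#'   method column.
#' @return Data frame (class `comparison_report`): `method`,
#'   `psnr_mean`, `psnr_sd`, `ssim_mean`, `n`.
#' @export
compare_methods <- function(model, test_pairs, config = metric_config(),
                            extra = NULL) {
  if (length(test_pairs) < 1L) stop("empty test set", call. = FALSE)
  recons <- list(cubic_interpolation = lapply(test_pairs, `[[`, "lr"))
  if (!is.null(model)) {
    stopifnot(inherits(model, "srcnn_model"))
    recons$srcnn <- lapply(test_pairs,
                           function(p) sr_forward(model, p$lr))
  }
  for (nm in names(extra)) recons[[nm]] <- extra[[nm]]
  rows <- lapply(names(recons), function(nm) {
    ps <- vapply(seq_along(test_pairs), function(i)
      psnr(test_pairs[[i]]$hr, recons[[nm]][[i]], config), 0)
    ss <- vapply(seq_along(test_pairs), function(i)
      ssim(test_pairs[[i]]$hr, recons[[nm]][[i]], config)$ssim, 0)
    sd_p <- if (length(ps) > 1L) stats::sd(ps) else 0
    data.frame(method = nm, psnr_mean = mean(ps), psnr_sd = sd_p,
               ssim_mean = mean(ss), n = length(ps))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_report", class(out))
  out
}

#' Sweep the number of convolution kernels
#'
#' Trains one model per entry of `kernel_counts` with everything else
#' held fixed and returns the aligned training histories.  The count
#' can be interpreted as the hidden channel width (`"width"`, default:
#' every hidden layer gets `count` kernels) or as the hidden layer
#' count (`"depth"`: `count` hidden mapping layers at the base width).
#'
#' @param base_config A [training_config()] providing everything but
#'   the swept parameter.
#' @param kernel_counts Integer vector of counts to sweep.
#' @param patches,val_pairs As in [sr_train()].
#' @param dimension `"width"` or `"depth"`.
#' @return Named list of history data frames (`k<count>`).
#' @export
kernel_sweep <- function(base_config, kernel_counts, patches, val_pairs,
                         dimension = c("width", "depth")) {
  dimension <- match.arg(dimension)
  stopifnot(length(kernel_counts) >= 1L)
  counts <- as.integer(kernel_counts)
  out <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    count <- counts[i]
    cfg <- base_config
    if (dimension == "width") {
      cfg$channels <- rep(count, length(cfg$channels))
    } else {
      k <- cfg$kernels
      k_mid <- if (length(k) > 2L) k[2] else 1L
      cfg$kernels <- c(k[1], rep(k_mid, count - 1L), k[length(k)])
      cfg$channels <- rep(cfg$channels[1], count)
    }
    out[[i]] <- sr_train(cfg, patches, val_pairs)$history
  }
  names(out) <- paste0("k", counts)
  out
}

#' First iteration at which a history reaches a PSNR level
#'
#' Convergence-speed summary for training curves: the earliest logged
#' iteration whose validation PSNR is at least `level`; `Inf` if the
#' curve never reaches it.
#'
#' @param history A history data frame from [sr_train()].
#' @param level PSNR level in dB.
#' @return Iteration number or `Inf`.
#' @export
iterations_to_reach <- function(history, level) {
  hit <- which(history$val_psnr >= level)
  if (length(hit) == 0L) return(Inf)
  history$iteration[hit[1]]
}

#' Plot training curves
#'
#' Renders validation-PSNR-versus-iteration curves for one or more
#' histories to a PNG file (or the active device).
#'
#' @param histories Named list of history data frames.
#' @param path Optional PNG output path.
#' @return `invisible(NULL)`.
#' @export
plot_history <- function(histories, path = NULL) {
  if (inherits(histories, "data.frame")) histories <- list(run = histories)
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 500)
    on.exit(grDevices::dev.off())
  }
  rng_y <- range(unlist(lapply(histories, `[[`, "val_psnr")), finite = TRUE)
  rng_x <- range(unlist(lapply(histories, `[[`, "iteration")))
  graphics::plot(NA, xlim = rng_x, ylim = rng_y, xlab = "iteration",
                 ylab = "validation PSNR (dB)")
  for (i in seq_along(histories))
    graphics::lines(histories[[i]]$iteration, histories[[i]]$val_psnr,
                    col = i, lwd = 2)
  graphics::legend("bottomright", legend = names(histories),
                   col = seq_along(histories), lwd = 2, bty = "n")
  invisible(NULL)
}
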