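#' Normalize an image by its maximum intensity
#'
#' Divides every pixel by the image maximum so the output peaks at 1.
#' This is the reference normalization all downstream stages assume
#' (metric configs default to a peak/range of 1).  The map is monotone,
#' idempotent, and rejects all-zero images rather than silently
#' returning zeros: a zero maximum makes the division undefined and
#' almost always indicates an upstream loading bug.
#'
#' @param raw Numeric matrix with non-negative entries and at least one
#'   strictly positive pixel.
#' @return Numeric matrix with maximum exactly 1.
#' @examples
#' normalize_image(matrix(c(1, 2, 3, 4), 2))
#' @export
normalize_image <- function(raw) {
  stopifnot(is.matrix(raw))
  if (any(raw < 0)) stop("negative intensities are not allowed", call. = FALSE)
  m <- max(raw)
  if (m == 0)
    stop("cannot normalize an all-zero image (zero maximum)", call. = FALSE)
  raw / m
}

#' Extract aligned low-/high-resolution training patches
#'
#' Slides a `patch_size` window over both images on a common stride
#' grid and collects every axis-aligned patch, row-major (left-to-right,
#' then top-to-bottom).  The low-resolution image must already be on the
#' high-resolution grid (pre-upsampling convention), so the two patch
#' collections align 1:1 with equal dimensions.  The number of patches
#' is `(floor((H - p) / s) + 1) * (floor((W - p) / s) + 1)`.
#'
#' @param lr,hr Numeric matrices of identical dimensions.
#' @param patch_size Patch side length in pixels.
#' @param stride Step between patch origins in pixels.
#' @return A `patch_set`: list with `lr`, `hr` (arrays
#'   `patch_size x patch_size x n`), `patch_size`, `stride`, `n`.
#' @export
extract_patches <- function(lr, hr, patch_size = 32L, stride = 16L) {
  stopifnot(is.matrix(lr), is.matrix(hr))
  if (!identical(dim(lr), dim(hr)))
    stop("lr and hr must have identical dimensions", call. = FALSE)
  p <- as.integer(patch_size); s <- as.integer(stride)
  if (p > nrow(hr) || p > ncol(hr))
    stop("patch_size exceeds image dimensions", call. = FALSE)
  if (s < 1L) stop("stride must be >= 1", call. = FALSE)
  rows <- seq(1L, nrow(hr) - p + 1L, by = s)
  cols <- seq(1L, ncol(hr) - p + 1L, by = s)
  n <- length(rows) * length(cols)
  lr_a <- array(0, c(p, p, n)); hr_a <- array(0, c(p, p, n))
  k <- 0L
  for (r in rows) for (cc in cols) {   # row-major: sweep columns inner
    k <- k + 1L
    lr_a[, , k] <- lr[r:(r + p - 1L), cc:(cc + p - 1L)]
    hr_a[, , k] <- hr[r:(r + p - 1L), cc:(cc + p - 1L)]
  }
  structure(list(lr = lr_a, hr = hr_a, patch_size = p, stride = s, n = n),
            class = "patch_set")
}

#' Merge several patch sets
#'
#' @param ... `patch_set` objects with equal patch sizes.
#' @return A single combined `patch_set`.
#' @export
combine_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "patch_set")) sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, TRUE, "patch_set")))
  p <- unique(vapply(sets, `[[`, 0L, "patch_size"))
  if (length(p) != 1L) stop("patch sizes differ", call. = FALSE)
  n <- sum(vapply(sets, `[[`, 0L, "n"))
  lr <- array(unlist(lapply(sets, `[[`, "lr")), c(p, p, n))
  hr <- array(unlist(lapply(sets, `[[`, "hr")), c(p, p, n))
  structure(list(lr = lr, hr = hr, patch_size = p,
                 stride = sets[[1]]$stride, n = n), class = "patch_set")
}

#' Dihedral data augmentation
#'
#' Expands a patch set with the 8 symmetries of the square (identity,
#' rotations by 90/180/270 degrees, horizontal and vertical flips, and
#' the two transpositions), applied identically to each low-/high-
#' resolution pair — the standard augmentation for super-resolution
#' training, where image statistics are orientation-free.
#'
#' @param patches A `patch_set`.
#' @return A `patch_set` with `8 * n` aligned pairs; variant `v` of
#'   input patch `k` is at index `(k - 1) * 8 + v`.
#' @export
augment_patches <- function(patches) {
  stopifnot(inherits(patches, "patch_set"))
  p <- patches$patch_size; n <- patches$n
  lr <- array(0, c(p, p, 8L * n)); hr <- array(0, c(p, p, 8L * n))
  for (k in seq_len(n)) {
    vl <- dihedral_variants(patches$lr[, , k])
    vh <- dihedral_variants(patches$hr[, , k])
    idx <- (k - 1L) * 8L + seq_len(8L)
    for (v in 1:8) { lr[, , idx[v]] <- vl[[v]]; hr[, , idx[v]] <- vh[[v]] }
  }
  structure(list(lr = lr, hr = hr, patch_size = p, stride = patches$stride,
                 n = 8L * n), class = "patch_set")
}

#' The 8 dihedral variants of a square matrix
#'
#' @param m Square numeric matrix.
#' @return List of 8 matrices: identity, rot90, rot180, rot270,
#'   horizontal flip, vertical flip, transpose, anti-transpose.
#' @export
dihedral_variants <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  rot90 <- function(x) t(x)[ncol(x):1, , drop = FALSE]
  r1 <- rot90(m); r2 <- rot90(r1); r3 <- rot90(r2)
  list(m, r1, r2, r3,
       m[, ncol(m):1, drop = FALSE],   # horizontal flip
       m[nrow(m):1, , drop = FALSE],   # vertical flip
       t(m),
       rot90(rot90(t(m))))             # anti-transpose
}

#' Reassemble an image from non-overlapping patches
#'
#' Inverse of [extract_patches()] when `stride == patch_size` and the
#' patch grid tiles the image exactly.
#'
#' @param patches A `patch_set` (the `hr` side is used).
#' @param height,width Dimensions of the original image.
#' @param which Either `"hr"` (default) or `"lr"`.
#' @return The reconstructed numeric matrix.
#' @export
reassemble_patches <- function(patches, height, width, which = "hr") {
  stopifnot(inherits(patches, "patch_set"))
  p <- patches$patch_size
  if (patches$stride != p)
    stop("reassembly requires stride == patch_size", call. = FALSE)
  if (height %% p != 0L || width %% p != 0L)
    stop("patches do not tile the requested dimensions", call. = FALSE)
  a <- patches[[which]]
  out <- matrix(0, height, width)
  k <- 0L
  for (r in seq(1L, height - p + 1L, by = p))
    for (cc in seq(1L, width - p + 1L, by = p)) {
      k <- k + 1L
      out[r:(r + p - 1L), cc:(cc + p - 1L)] <- a[, , k]
    }
  out
}

#' Save / load a patch set as plain text with a JSON manifest
#'
#' Patches are stored flattened, one patch per row, in two
#' whitespace-separated text files (`<stem>_lr.txt`, `<stem>_hr.txt`)
#' with a JSON manifest (`<stem>.json`) recording patch size, stride
#' and count.
#'
#' @param patches A `patch_set`.
#' @param stem Path stem (no extension).
#' @return `stem`, invisibly.
#' @export
save_patch_set <- function(patches, stem) {
  stopifnot(inherits(patches, "patch_set"))
  flat <- function(a) t(apply(a, 3, as.numeric))
  utils::write.table(flat(patches$lr), paste0(stem, "_lr.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(flat(patches$hr), paste0(stem, "_hr.txt"),
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(patch_size = patches$patch_size,
                            stride = patches$stride, n = patches$n),
                       paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname save_patch_set
#' @export
load_patch_set <- function(stem) {
  man <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  p <- man$patch_size
  unflat <- function(path) {
    m <- as.matrix(utils::read.table(path))
    array(t(m), c(p, p, man$n))
  }
  structure(list(lr = unflat(paste0(stem, "_lr.txt")),
                 hr = unflat(paste0(stem, "_hr.txt")),
                 patch_size = p, stride = man$stride, n = man$n),
            class = "patch_set")
}
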