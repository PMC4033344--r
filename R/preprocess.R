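#' Fit a per-pixel Gaussian background model
#'
#' Estimates a background model from a stack of raw grayscale frames by
#' taking, at every pixel, the mean intensity and the standard deviation
#' of intensity across frames. Foreground decisions later compare a frame
#' against `mean +/- threshold_k * spread`.
#'
#' @param frames List of numeric matrices (rows x cols), all the same size.
#' @param threshold_k Number of spreads beyond which a pixel is declared
#'   foreground during segmentation. Default 2.5.
#' @param spread_floor Lower bound applied to the per-pixel spread when
#'   thresholding, so that pixels with zero variance (a perfectly static
#'   background) do not make the decision rule degenerate. Default 1e-3
#'   on the `[0, 1]` intensity scale.
#' @return An object of class `gait_background` with elements `mean`,
#'   `sd` (population s.d., divisor `n`), `threshold_k`, `spread_floor`.
#' @examples
#' bg <- fit_background(list(matrix(0, 4, 4), matrix(0.2, 4, 4)))
#' range(bg$mean)
#' @export
fit_background <- function(frames, threshold_k = 2.5, spread_floor = 1e-3) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("need at least 2 frames to fit a background model")
  dims <- dim(frames[[1L]])
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || !is.numeric(f))
      stop("frame ", i, " is not a numeric matrix")
    if (!identical(dim(f), dims))
      stop("frame ", i, " has dimensions ", paste(dim(f), collapse = "x"),
           ", expected ", paste(dims, collapse = "x"))
    if (!all(is.finite(f))) stop("frame ", i, " contains non-finite values")
  }
  n <- length(frames)
  s <- Reduce(`+`, frames)
  s2 <- Reduce(`+`, lapply(frames, function(f) f * f))
  mu <- s / n
  v <- pmax(s2 / n - mu * mu, 0)
  structure(list(mean = mu, sd = sqrt(v),
                 threshold_k = threshold_k, spread_floor = spread_floor),
            class = "gait_background")
}

#' Segment a walking figure from a frame by background subtraction
#'
#' Blurs the frame with a Gaussian filter, marks as foreground every pixel
#' whose blurred intensity differs from the background mean by more than
#' `threshold_k` spreads, and keeps the largest connected component so
#' that isolated noise speckles do not survive. The returned mask is raw:
#' it has not yet been height-normalized or aligned
#' (see [normalize_silhouette()]).
#'
#' @param frame Numeric matrix with the same dimensions as the background.
#' @param bg A `gait_background` from [fit_background()].
#' @param blur_sigma Gaussian blur s.d. in pixels; `0` disables blurring.
#' @param keep_largest Keep only the largest 8-connected foreground
#'   component (default `TRUE`).
#' @return Binary 0/1 matrix of the same dimensions.
#' @export
segment_silhouette <- function(frame, bg, blur_sigma = 1, keep_largest = TRUE) {
  stopifnot(inherits(bg, "gait_background"))
  if (!identical(dim(frame), dim(bg$mean)))
    stop("frame dimensions do not match the background model")
  f <- if (blur_sigma > 0) EBImage::gblur(frame, sigma = blur_sigma) else frame
  spread <- pmax(bg$sd, bg$spread_floor)
  mask <- (abs(f - bg$mean) > bg$threshold_k * spread) * 1
  if (keep_largest && any(mask > 0)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    mask <- (lab == which.max(sizes)) * 1
  }
  if (!any(mask > 0)) stop("no subject detected: segmentation found no foreground")
  storage.mode(mask) <- "double"
  mask
}

#' Centroid of a binary silhouette
#'
#' Returns the mean foreground coordinate \eqn{x_c = (1/n)\sum x_i},
#' \eqn{y_c = (1/n)\sum y_i}, where the sum runs over the `n` foreground
#' pixels. Coordinates are 0-based with `x` the column and `y` the row
#' (top-left origin), and are real-valued (not rounded).
#'
#' @param mask Binary 0/1 matrix.
#' @return Named numeric vector `c(x = x_c, y = y_c)`.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 1] <- 1; m[3, 3] <- 1
#' compute_centroid(m)  # c(x = 1, y = 1)
#' @export
compute_centroid <- function(mask) {
  .check_binary(mask)
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot compute the centroid of an empty mask")
  c(x = mean(idx[, 2L]) - 1, y = mean(idx[, 1L]) - 1)
}

.check_binary <- function(mask) {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop("mask must be a numeric matrix")
  if (!all(mask %in% c(0, 1)))
    stop("mask must contain only 0/1 values")
  invisible(TRUE)
}

# Keys cubic-convolution kernel, a = -0.5 (the classic bicubic kernel).
.cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# Dense resampling operator mapping n_in samples to n_out by cubic
# convolution; output pixel centers are mapped to input coordinates with
# the standard half-pixel convention, edges clamped. Rows sum to 1.
.cubic_weights <- function(n_in, n_out) {
  s <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * s - 0.5          # 0-based input coords
  W <- matrix(0, n_out, n_in)
  base <- floor(src)
  for (k in -1:2) {
    j <- base + k                                   # 0-based tap index
    w <- .cubic_kernel(src - j)
    j <- pmin(pmax(j, 0), n_in - 1L)                # clamp at the border
    W[cbind(seq_len(n_out), j + 1L)] <-
      W[cbind(seq_len(n_out), j + 1L)] + w
  }
  W / rowSums(W)
}

#' Resize an image by bicubic (cubic-convolution) interpolation
#'
#' Separable Keys cubic convolution (a = -0.5). Used internally for
#' silhouette height normalization; exported because it is generally
#' useful for template-scale experiments.
#'
#' @param img Numeric matrix.
#' @param out_dim Integer vector `c(rows, cols)` of the output size.
#' @return Numeric matrix of size `out_dim`.
#' @export
resize_bicubic <- function(img, out_dim) {
  stopifnot(is.matrix(img), length(out_dim) == 2L, all(out_dim >= 1))
  Wr <- .cubic_weights(nrow(img), out_dim[1L])
  Wc <- .cubic_weights(ncol(img), out_dim[2L])
  Wr %*% img %*% t(Wc)
}

#' Height-normalize and centroid-align a silhouette on a fixed canvas
#'
#' Crops the mask to its bounding box, rescales it by bicubic
#' interpolation so the bounding-box height equals `target_height` with
#' the aspect ratio preserved, re-binarizes at 0.5, and places the result
#' on an `H x W` zero canvas so that its centroid lands on the canvas
#' center (rounded to the nearest pixel, ties toward negative infinity).
#' After this step any two frames of a sequence are mutually aligned and
#' frame differencing is a plain per-pixel comparison.
#'
#' @param mask Binary 0/1 matrix with at least one foreground pixel.
#' @param target_height Height in pixels of the normalized silhouette.
#'   Default 200.
#' @param canvas Integer vector `c(H, W)`; default `c(240, 320)`.
#' @return Binary 0/1 matrix of dimensions `canvas`.
#' @export
normalize_silhouette <- function(mask, target_height = 200,
                                 canvas = c(240, 320)) {
  .check_binary(mask)
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot normalize an empty mask")
  H <- as.integer(canvas[1L]); W <- as.integer(canvas[2L])
  if (target_height > H)
    stop("target_height exceeds canvas height")
  r0 <- min(idx[, 1L]); r1 <- max(idx[, 1L])
  c0 <- min(idx[, 2L]); c1 <- max(idx[, 2L])
  crop <- mask[r0:r1, c0:c1, drop = FALSE]
  scale <- target_height / nrow(crop)
  new_w <- max(1L, as.integer(round(ncol(crop) * scale)))
  if (new_w > W)
    stop("rescaled silhouette is wider (", new_w, " px) than the canvas (",
         W, " px); use a larger canvas or a smaller target_height")
  resized <- (resize_bicubic(crop, c(as.integer(target_height), new_w)) >= 0.5) * 1
  if (!any(resized > 0)) stop("silhouette vanished after rescaling")
  ctr <- compute_centroid(resized)                  # 0-based (x, y)
  target <- c(x = (W - 1) / 2, y = (H - 1) / 2)
  # nearest integer, ties toward -Inf
  shift <- ceiling(target - ctr - 0.5)
  out <- matrix(0, H, W)
  rows <- seq_len(nrow(resized)) + shift["y"]
  cols <- seq_len(ncol(resized)) + shift["x"]
  keep_r <- rows >= 1 & rows <= H
  keep_c <- cols >= 1 & cols <= W
  out[rows[keep_r], cols[keep_c]] <- resized[keep_r, keep_c, drop = FALSE]
  out
}
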