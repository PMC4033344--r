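#' Construct a silhouette sequence object
#'
#' Bundles a list of aligned binary frames sharing one canvas with its
#' identity labels. Frames are validated to be binary and of identical
#' dimensions.
#'
#' @param frames List of 0/1 matrices, all the same size, length >= 1.
#' @param subject_id,sequence_id Character labels.
#' @param view_angle View angle in degrees (90 = side view).
#' @return Object of class `gait_sequence`.
#' @export
gait_sequence <- function(frames, subject_id = "unknown",
                          sequence_id = "seq", view_angle = 90) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("a sequence needs at least one frame")
  dims <- dim(frames[[1L]])
  for (i in seq_along(frames)) {
    .check_binary(frames[[i]])
    if (!identical(dim(frames[[i]]), dims))
      stop("frame ", i, " has dimensions ",
           paste(dim(frames[[i]]), collapse = "x"),
           " but frame 1 has ", paste(dims, collapse = "x"))
  }
  structure(list(frames = frames, subject_id = as.character(subject_id),
                 sequence_id = as.character(sequence_id),
                 view_angle = view_angle),
            class = "gait_sequence")
}

#' @export
print.gait_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<gait_sequence> subject=%s sequence=%s view=%s: %d frames of %dx%d\n",
              x$subject_id, x$sequence_id, x$view_angle,
              length(x$frames), d[1L], d[2L]))
  invisible(x)
}

#' @export
length.gait_sequence <- function(x) length(x$frames)

#' Gait differential image of two adjacent silhouettes
#'
#' The per-pixel inequality indicator: 0 where the two aligned frames
#' agree, 1 where they differ (XOR for binary inputs). Symmetric in its
#' arguments.
#'
#' @param a,b Binary 0/1 matrices of identical dimensions.
#' @return Binary 0/1 matrix.
#' @export
differential_image <- function(a, b) {
  .check_binary(a); .check_binary(b)
  if (!identical(dim(a), dim(b)))
    stop("differential image requires frames of identical dimensions")
  (a != b) * 1
}

.seq_window <- function(seq, frames) {
  if (is.null(frames)) return(seq$frames)
  frames <- as.integer(frames)
  if (any(frames < 1L) || any(frames > length(seq$frames)))
    stop("frame window out of range")
  seq$frames[frames]
}

.new_template <- function(values, kind, n, seq) {
  structure(list(values = values, kind = kind, n_frames_used = n,
                 subject_id = seq$subject_id, sequence_id = seq$sequence_id,
                 view_angle = seq$view_angle),
            class = "gait_template")
}

#' Average gait differential image (AGDI)
#'
#' The mean of the N-1 differential images between adjacent frames:
#' \deqn{G(x,y) = \frac{1}{N-1}\sum_{j=1}^{N-1} D_j(x,y).}
#' It highlights pixels where the silhouette changes between frames, so
#' it preserves both the kinetic information (limb swing bands) and, at
#' the silhouette boundary, the static body shape.
#'
#' @param seq A `gait_sequence` with at least 2 frames in the window.
#' @param frames Optional integer vector of frame indices to use
#'   (default: whole sequence).
#' @return `gait_template` with `kind = "agdi"`, values in `[0, 1]`.
#' @export
build_agdi <- function(seq, frames = NULL) {
  stopifnot(inherits(seq, "gait_sequence"))
  fr <- .seq_window(seq, frames)
  n <- length(fr)
  if (n < 2L) stop("AGDI needs at least 2 frames")
  acc <- matrix(0, nrow(fr[[1L]]), ncol(fr[[1L]]))
  for (j in seq_len(n - 1L)) acc <- acc + (fr[[j]] != fr[[j + 1L]])
  .new_template(acc / (n - 1L), "agdi", n, seq)
}

#' Gait energy image (GEI)
#'
#' The per-pixel mean of the aligned binary silhouettes themselves (the
#' real-valued template): `GEI(x, y)` is the fraction of frames with
#' foreground at `(x, y)`.
#'
#' @inheritParams build_agdi
#' @return `gait_template` with `kind = "gei"`, values in `[0, 1]`.
#' @export
build_gei <- function(seq, frames = NULL) {
  stopifnot(inherits(seq, "gait_sequence"))
  fr <- .seq_window(seq, frames)
  n <- length(fr)
  if (n < 1L) stop("GEI needs at least 1 frame")
  .new_template(Reduce(`+`, fr) / n, "gei", n, seq)
}

#' @export
print.gait_template <- function(x, ...) {
  cat(sprintf("<gait_template:%s> subject=%s sequence=%s %dx%d from %d frames\n",
              x$kind, x$subject_id, x$sequence_id,
              nrow(x$values), ncol(x$values), x$n_frames_used))
  invisible(x)
}

#' @export
plot.gait_template <- function(x, ...) {
  v <- x$values
  graphics::image(t(v)[, nrow(v):1, drop = FALSE], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(v) / ncol(v),
                  main = sprintf("%s (%s/%s)", toupper(x$kind),
                                 x$subject_id, x$sequence_id), ...)
  invisible(x)
}

#' Estimate the gait cycle length from the silhouette-width signal
#'
#' The silhouette width (foreground column extent) oscillates with the
#' stride. The cycle length is taken from the local maxima of the width
#' autocorrelation: the first peak gives a candidate period, and the
#' full cycle (twice that lag) is preferred when its correlation is
#' comparable, since the two steps of a stride look alike in width. A
#' convenience for choosing template windows; templates themselves are
#' built over caller-specified windows.
#'
#' @param seq A `gait_sequence` with at least 8 frames.
#' @param max_lag Largest lag considered (default half the sequence
#'   length).
#' @return Integer estimate of the cycle length in frames.
#' @export
estimate_cycle_length <- function(seq, max_lag = NULL) {
  stopifnot(inherits(seq, "gait_sequence"))
  n <- length(seq$frames)
  if (n < 8L) stop("cycle estimation needs at least 8 frames")
  width <- vapply(seq$frames, function(f) {
    cols <- which(colSums(f) > 0)
    if (length(cols) == 0L) 0 else diff(range(cols)) + 1
  }, numeric(1))
  if (is.null(max_lag)) max_lag <- floor(n / 2)
  ac <- stats::acf(width, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[-1L]
  # candidate periods: local maxima of the autocorrelation beyond the
  # adjacent-frame lags
  k <- length(ac)
  if (k < 4L) stop("sequence too short for cycle estimation")
  is_max <- vapply(3:(k - 1L), function(i)
    ac[i] >= ac[i - 1L] && ac[i] >= ac[i + 1L], logical(1))
  cand <- (3:(k - 1L))[is_max]
  if (length(cand) == 0L) stop("no periodic structure in the width signal")
  p <- cand[1L]
  # the width signal repeats every half cycle (the two steps of a stride
  # look alike); prefer the full cycle when its correlation holds up
  if (2L * p <= k && ac[2L * p] >= ac[p] - 0.05) p <- 2L * p
  as.integer(p)
}

#' Write / read a gait template as 16-bit grayscale TIFF with sidecar
#'
#' Values in `[0, 1]` are stored as `round(value * 65535)` in a 16-bit
#' grayscale TIFF; provenance (kind, labels, frame count) goes to a
#' sidecar text header `<file>.txt`. The round-trip is bit-exact at the
#' 16-bit quantization: `write_template()` itself quantizes the values so
#' that what is read back equals what was written.
#'
#' @param template A `gait_template`.
#' @param file Output path (`.tif`).
#' @return `write_template()` returns the (quantized) template invisibly;
#'   `read_template()` returns a `gait_template`.
#' @export
write_template <- function(template, file) {
  stopifnot(inherits(template, "gait_template"))
  v <- round(template$values * 65535) / 65535
  tiff::writeTIFF(v, file, bits.per.sample = 16L, compression = "none")
  hdr <- c(kind = template$kind,
           subject_id = template$subject_id,
           sequence_id = template$sequence_id,
           view_angle = as.character(template$view_angle),
           n_frames_used = as.character(template$n_frames_used),
           rows = as.character(nrow(v)), cols = as.character(ncol(v)))
  writeLines(paste(names(hdr), hdr, sep = "="), paste0(file, ".txt"))
  template$values <- v
  invisible(template)
}

#' @rdname write_template
#' @export
read_template <- function(file) {
  v <- tiff::readTIFF(file)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  hdr_file <- paste0(file, ".txt")
  hdr <- list(kind = "agdi", subject_id = "unknown",
              sequence_id = "seq", view_angle = "90", n_frames_used = "0")
  if (file.exists(hdr_file)) {
    kv <- strsplit(readLines(hdr_file), "=", fixed = TRUE)
    for (p in kv) if (length(p) == 2L) hdr[[p[[1L]]]] <- p[[2L]]
  }
  structure(list(values = v, kind = hdr$kind,
                 n_frames_used = as.integer(hdr$n_frames_used),
                 subject_id = hdr$subject_id, sequence_id = hdr$sequence_id,
                 view_angle = as.numeric(hdr$view_angle)),
            class = "gait_template")
}
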