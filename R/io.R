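.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  toks <- character(0)
  while (length(toks) < 3L) {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("truncated PGM header: ", path)
    ln <- sub("#.*$", "", ln)
    toks <- c(toks, strsplit(trimws(ln), "\\s+")[[1L]])
    toks <- toks[nzchar(toks)]
  }
  w <- as.integer(toks[1L]); h <- as.integer(toks[2L])
  maxval <- as.integer(toks[3L])
  n <- w * h
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  matrix(vals, h, w, byrow = TRUE) / maxval
}

.write_pgm <- function(mat, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(mat), nrow(mat)), "255"), con)
  writeBin(as.raw(round(t(mat) * 255)), con)
}

.read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                pgm = .read_pgm(path),
                stop("unsupported frame format '", ext, "': ", path))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Read a silhouette sequence from a directory of frames
#'
#' A sequence is a directory of PNG/PGM frames; time order is given by
#' the zero-padded numeric part of the filenames (plain lexicographic
#' order, with a warning, when names are not numeric). Frames are
#' binarized at 0.5. CASIA-style nested layouts
#' `subject/condition/angle/` are parsed into labels from the trailing
#' path segments.
#'
#' @param dir Directory containing the frames.
#' @param binarize Threshold frames at 0.5 into 0/1 masks (default
#'   `TRUE`).
#' @return A `gait_sequence`.
#' @export
read_sequence <- function(dir, binarize = TRUE) {
  if (!dir.exists(dir)) stop("no such sequence directory: ", dir)
  files <- list.files(dir, pattern = "\\.(png|pgm)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) stop("empty sequence directory: ", dir)
  nums <- suppressWarnings(as.integer(gsub("\\D", "", basename(files))))
  if (anyNA(nums) || anyDuplicated(nums[!is.na(nums)])) {
    warning("non-numeric frame names in ", dir,
            "; using lexicographic order")
    files <- sort(files)
  } else files <- files[order(nums)]
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- tryCatch(.read_frame(files[[i]]),
                    error = function(e) stop("unreadable frame ",
                                             basename(files[[i]]), ": ",
                                             conditionMessage(e)))
    if (i > 1L && !identical(dim(img), dim(frames[[1L]])))
      stop("frame ", basename(files[[i]]), " has dimensions ",
           paste(dim(img), collapse = "x"), ", expected ",
           paste(dim(frames[[1L]]), collapse = "x"))
    frames[[i]] <- if (binarize) (img >= 0.5) * 1 else img
  }
  parts <- rev(strsplit(normalizePath(dir, mustWork = FALSE),
                        .Platform$file.sep, fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  # CASIA-style subject/sequence/angle layout: leaf directory is the
  # numeric view angle; otherwise the leaf names the subject
  if (grepl("^[0-9]+$", parts[1L]) && length(parts) >= 3L) {
    gait_sequence(frames, subject_id = parts[3L], sequence_id = parts[2L],
                  view_angle = as.numeric(parts[1L]))
  } else {
    gait_sequence(frames, subject_id = parts[1L], sequence_id = "seq",
                  view_angle = 90)
  }
}

#' Write a silhouette sequence as zero-padded PNG frames
#'
#' Inverse of [read_sequence()]: binary masks round-trip losslessly.
#'
#' @param seq A `gait_sequence`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sequence <- function(seq, dir) {
  stopifnot(inherits(seq, "gait_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_along(seq$frames))
    png::writePNG(seq$frames[[j]], file.path(dir, sprintf("%04d.png", j)))
  invisible(dir)
}

.default_config <- function() {
  list(canvas_height = 128L, canvas_width = 96L, target_height = 200L,
       blur_sigma = 1, threshold_k = 2.5, spread_floor = 1e-3,
       kind = "agdi", method = "2dpca", d = 20L,
       protocol = "plain", seed = 1L,
       n_subjects = 10L, seqs_per_subject = 2L, frames_per_seq = 40L,
       flip_prob = 0.005, jitter_scale = 0.02,
       gallery_dir = "", probe_dir = "")
}

#' Read / write a flat run configuration
#'
#' The configuration is a flat YAML map of scalars holding every
#' pipeline default (canvas, template kind, feature method, d,
#' protocol, seed, paths). Unknown keys are rejected; the round-trip is
#' lossless.
#'
#' @param file Path to the YAML config.
#' @return Named list of configuration values.
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  def <- .default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(def, cfg)
  for (k in names(def))
    if (is.integer(def[[k]])) out[[k]] <- as.integer(out[[k]])
  out
}

#' @rdname read_config
#' @param config Named list as returned by `read_config()`.
#' @export
write_config <- function(config, file) {
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  yaml::write_yaml(config, file)
  invisible(file)
}

#' Run the full recognition pipeline from a configuration
#'
#' Orchestrates data loading (or synthetic generation when no gallery
#' directory is configured), template construction, feature extraction
#' and evaluation, and returns the same `gait_eval` report that the
#' stage-by-stage calls produce. With `gallery_dir`/`probe_dir` set,
#' each is a directory of sequence subdirectories of PNG/PGM frames.
#'
#' @param config Named list from [read_config()] (or
#'   [default_config()]).
#' @return A `gait_eval` report.
#' @export
run_pipeline <- function(config = default_config()) {
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(def, config)
  if (nzchar(config$gallery_dir)) {
    if (!dir.exists(config$gallery_dir))
      stop("pipeline stage 'load': no such directory ", config$gallery_dir)
    if (!dir.exists(config$probe_dir))
      stop("pipeline stage 'load': no such directory ", config$probe_dir)
    read_all <- function(root) {
      dirs <- list.dirs(root, recursive = FALSE)
      if (length(dirs) == 0L) stop("pipeline stage 'load': ", root,
                                   " contains no sequence directories")
      lapply(dirs, read_sequence)
    }
    gallery <- read_all(config$gallery_dir)
    probes <- read_all(config$probe_dir)
  } else {
    pop <- generate_population(config$n_subjects, config$seqs_per_subject,
                               config$frames_per_seq, seed = config$seed,
                               canvas = c(config$canvas_height,
                                          config$canvas_width),
                               flip_prob = config$flip_prob,
                               jitter_scale = config$jitter_scale)
    first <- vapply(pop, function(s) s$sequence_id == "seq01", logical(1))
    gallery <- pop[first]
    probes <- pop[!first]
  }
  evaluate_recognition(gallery, probes, kind = config$kind,
                       method = config$method, d = config$d,
                       protocol = config$protocol)
}

#' @rdname read_config
#' @export
default_config <- function() .default_config()
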