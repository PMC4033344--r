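#' Assemble a gallery of enrolled feature matrices
#'
#' @param features List of `gait_features`, all of identical shape.
#' @param subject_ids Character vector of subject labels, one per entry;
#'   defaults to the `subject_id` attributes of `features`.
#' @return Object of class `gait_gallery`.
#' @export
gait_gallery <- function(features, subject_ids = NULL) {
  if (!is.list(features) || length(features) < 1L)
    stop("gallery needs at least one entry")
  if (is.null(subject_ids))
    subject_ids <- vapply(features, function(f)
      as.character(attr(f, "subject_id") %||% "unknown"), character(1))
  if (length(subject_ids) != length(features))
    stop("one subject id per gallery entry required")
  sh <- dim(unclass(features[[1L]]))
  for (i in seq_along(features))
    if (!identical(dim(unclass(features[[i]])), sh))
      stop("gallery entry ", i, " has mismatched feature shape")
  structure(list(features = features, subject_ids = as.character(subject_ids)),
            class = "gait_gallery")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gait_gallery <- function(x, ...) {
  cat(sprintf("<gait_gallery> %d entries, %d distinct subjects\n",
              length(x$features), length(unique(x$subject_ids))))
  invisible(x)
}

#' @export
length.gait_gallery <- function(x) length(x$features)

#' Identify a probe by nearest-neighbour matching
#'
#' Computes the feature distance from the probe to every gallery entry
#' and assigns the probe to the subject at minimum distance. Ties are
#' broken by gallery insertion order (first entry wins; the ordering is
#' a stable sort).
#'
#' @param probe `gait_features` matching the gallery feature shape.
#' @param gallery A `gait_gallery`.
#' @return List with `subject_id` (the decision) and `ranking`, a
#'   data.frame with columns `subject_id`, `distance` sorted by
#'   increasing distance.
#' @export
identify_probe <- function(probe, gallery) {
  stopifnot(inherits(gallery, "gait_gallery"))
  if (length(gallery$features) == 0L) stop("empty gallery")
  d <- vapply(gallery$features, feature_distance, numeric(1), b = probe)
  ord <- order(d)                                   # stable: ties keep order
  ranking <- data.frame(subject_id = gallery$subject_ids[ord],
                        distance = d[ord], stringsAsFactors = FALSE)
  list(subject_id = ranking$subject_id[1L], ranking = ranking)
}

#' Similarity between two feature matrices
#'
#' Defined as the negative of the feature distance, so it is maximal
#' (zero) exactly when the matrices are equal.
#'
#' @inheritParams feature_distance
#' @return Non-positive scalar.
#' @export
similarity <- function(a, b) -feature_distance(a, b)

#' Z-normed similarities of a probe against a gallery
#'
#' The raw similarities of the probe to every gallery entry are
#' standardized by their own mean and standard deviation (sample s.d.,
#' divisor M - 1) across the gallery. Z-norming is a per-probe monotone
#' increasing transform, so it never changes which gallery entry ranks
#' first; it makes scores comparable across probes for a global
#' verification threshold.
#'
#' @param probe `gait_features`.
#' @param gallery A `gait_gallery` with at least 2 entries.
#' @return data.frame with columns `subject_id`, `similarity` (raw) and
#'   `z_similarity`.
#' @export
znorm_similarities <- function(probe, gallery) {
  stopifnot(inherits(gallery, "gait_gallery"))
  if (length(gallery$features) < 2L)
    stop("z-norming needs a gallery of at least 2 entries")
  s <- vapply(gallery$features, similarity, numeric(1), b = probe)
  sd_s <- stats::sd(s)
  if (!is.finite(sd_s) || sd_s == 0)
    stop("degenerate probe: all gallery similarities are equal")
  data.frame(subject_id = gallery$subject_ids,
             similarity = s,
             z_similarity = (s - mean(s)) / sd_s,
             stringsAsFactors = FALSE)
}

#' ROC curve and equal error rate from genuine/impostor scores
#'
#' Sweeps an acceptance threshold t over the union of the observed
#' scores (plus an endpoint above the maximum): a trial is accepted when
#' its score is >= t, so `FAR(t)` is the fraction of impostor scores
#' >= t and `FRR(t)` the fraction of genuine scores < t. The EER is the
#' common value at the crossing `FAR = FRR`, linearly interpolated
#' between the two bracketing thresholds.
#'
#' @param genuine,impostor Non-empty numeric score vectors (higher =
#'   more similar).
#' @return List with `roc` (data.frame `threshold`, `far`, `frr`) and
#'   `eer`.
#' @export
roc_and_eer <- function(genuine, impostor) {
  genuine <- as.numeric(genuine); impostor <- as.numeric(impostor)
  if (length(genuine) == 0L) stop("empty genuine score list")
  if (length(impostor) == 0L) stop("empty impostor score list")
  thr <- sort(unique(c(genuine, impostor)))
  thr <- c(thr, thr[length(thr)] + 1)               # all-reject endpoint
  sg <- sort(genuine); si <- sort(impostor)
  # counts of scores strictly below each threshold, via sorted search
  far <- 1 - findInterval(thr, si, left.open = TRUE) / length(si)
  frr <- findInterval(thr, sg, left.open = TRUE) / length(sg)
  g <- far - frr                                    # non-increasing in t
  i <- which(g <= 0)[1L]
  if (is.na(i)) { eer <- far[length(far)]           # never crosses: degenerate
  } else if (i == 1L) { eer <- frr[1L]
  } else {
    a <- g[i - 1L] / (g[i - 1L] - g[i])
    eer <- far[i - 1L] + a * (far[i] - far[i - 1L])
  }
  list(roc = data.frame(threshold = thr, far = far, frr = frr), eer = eer)
}

#' Run a full gallery/probe recognition experiment
#'
#' Builds one template per sequence, fits the projection basis on the
#' gallery templates only, projects gallery and probes, and reports the
#' cumulative match characteristic (CMC) from the identification
#' rankings together with verification metrics (ROC and EER) from
#' z-normed similarities, where the same-subject score of each probe is
#' genuine and all others are impostor.
#'
#' Under `protocol = "leave-one-out"`, for each probe the basis is
#' refitted with the same-subject gallery template left out of basis
#' training; the probe is still matched against every gallery entry,
#' including the left-out one.
#'
#' @param gallery_seqs,probe_seqs Lists of `gait_sequence`s with
#'   subject labels.
#' @param kind Template type, `"agdi"` (default) or `"gei"`.
#' @param method Feature extractor, `"2dpca"` (default) or `"pca"`.
#' @param d Number of projection axes (capped at the available rank for
#'   `"pca"`).
#' @param protocol `"plain"` (default) or `"leave-one-out"`.
#' @param gallery_frames,probe_frames Optional frame windows (integer
#'   vectors) applied to every gallery / probe sequence.
#' @return Object of class `gait_eval`: `cmc` (data.frame `rank`,
#'   `rate`), `roc`, `eer`, `rank1`, `decisions` (per-probe data.frame),
#'   `protocol` metadata.
#' @export
evaluate_recognition <- function(gallery_seqs, probe_seqs, kind = c("agdi", "gei"),
                                 method = c("2dpca", "pca"), d = 20,
                                 protocol = c("plain", "leave-one-out"),
                                 gallery_frames = NULL, probe_frames = NULL) {
  kind <- match.arg(kind); method <- match.arg(method)
  protocol <- match.arg(protocol)
  build <- if (kind == "agdi") build_agdi else build_gei
  g_tmpl <- lapply(gallery_seqs, build, frames = gallery_frames)
  p_tmpl <- lapply(probe_seqs, build, frames = probe_frames)
  g_ids <- vapply(g_tmpl, `[[`, character(1), "subject_id")

  fit_fun <- if (method == "2dpca") fit_basis else fit_pca_baseline
  proj_fun <- if (method == "2dpca") project_template else project_pca
  cap_d <- function(tmpls) {
    if (method == "pca") min(d, length(tmpls) - 1L) else d
  }

  score_probe <- function(pt) {
    if (protocol == "leave-one-out") {
      train <- g_tmpl[g_ids != pt$subject_id]
      if (length(train) < 2L) train <- g_tmpl
    } else train <- g_tmpl
    basis <- fit_fun(train, d = cap_d(train))
    gal <- gait_gallery(lapply(g_tmpl, proj_fun, basis = basis),
                        subject_ids = g_ids)
    pf <- proj_fun(pt, basis)
    id <- identify_probe(pf, gal)
    zn <- znorm_similarities(pf, gal)
    list(id = id, zn = zn)
  }

  n_rank <- length(g_tmpl)
  rank_hits <- integer(n_rank)
  genuine <- numeric(0); impostor <- numeric(0)
  decisions <- vector("list", length(p_tmpl))
  for (j in seq_along(p_tmpl)) {
    pt <- p_tmpl[[j]]
    res <- score_probe(pt)
    enrolled <- pt$subject_id %in% g_ids
    r <- if (enrolled) match(pt$subject_id, res$id$ranking$subject_id)
         else NA_integer_                            # forced error
    if (!is.na(r)) rank_hits[r] <- rank_hits[r] + 1L
    same <- res$zn$subject_id == pt$subject_id
    genuine <- c(genuine, res$zn$z_similarity[same])
    impostor <- c(impostor, res$zn$z_similarity[!same])
    decisions[[j]] <- data.frame(
      probe_subject = pt$subject_id, probe_sequence = pt$sequence_id,
      decision = res$id$subject_id, rank = r,
      min_distance = res$id$ranking$distance[1L],
      stringsAsFactors = FALSE)
  }
  decisions <- do.call(rbind, decisions)
  cmc <- cumsum(rank_hits) / length(p_tmpl)
  ver <- if (length(genuine) > 0L && length(impostor) > 0L)
    roc_and_eer(genuine, impostor) else list(roc = NULL, eer = NA_real_)
  structure(list(cmc = data.frame(rank = seq_len(n_rank), rate = cmc),
                 roc = ver$roc, eer = ver$eer, rank1 = cmc[1L],
                 decisions = decisions,
                 protocol = list(kind = kind, method = method, d = d,
                                 protocol = protocol,
                                 n_gallery = length(g_tmpl),
                                 n_probe = length(p_tmpl))),
            class = "gait_eval")
}

#' @export
print.gait_eval <- function(x, ...) {
  p <- x$protocol
  cat(sprintf("<gait_eval> %s + %s (d=%d, %s): %d gallery / %d probes\n",
              toupper(p$kind), toupper(p$method), p$d, p$protocol,
              p$n_gallery, p$n_probe))
  r5 <- x$cmc$rate[min(5L, nrow(x$cmc))]
  cat(sprintf("  rank-1 %.3f | rank-5 %.3f | EER %.3f\n",
              x$rank1, r5, x$eer))
  invisible(x)
}

#' @export
plot.gait_eval <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$cmc$rank, x$cmc$rate, type = "s", ylim = c(0, 1),
                 xlab = "rank", ylab = "cumulative match rate",
                 main = "CMC", ...)
  if (!is.null(x$roc)) {
    graphics::plot(x$roc$far, 1 - x$roc$frr, type = "l",
                   xlab = "FAR", ylab = "1 - FRR", main = "ROC", ...)
    graphics::abline(1, -1, lty = 3)
  }
  invisible(x)
}
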