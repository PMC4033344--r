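# run code under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards so package functions never disturb it
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Parameters of a synthetic side-view walker
#'
#' Describes one subject's body shape and gait style for the parametric
#' silhouette renderer: a 2-D side-view stick figure (elliptical torso,
#' circular head, two 2-segment legs and arms drawn as thick capsules)
#' whose joint angles are sinusoidal in time. All lengths are ratios of
#' the figure height so one parameter set works on any canvas.
#'
#' @param torso_width Torso width as a fraction of figure height.
#' @param torso_length Torso (neck-to-hip) length fraction.
#' @param head_radius Head radius fraction.
#' @param leg_length Hip-to-ground leg length fraction.
#' @param arm_length Shoulder-to-hand arm length fraction.
#' @param stride_amplitude Thigh swing amplitude in degrees, `[0, 60]`.
#' @param arm_amplitude Arm swing amplitude in degrees, `[0, 60]`.
#' @param cycle_frames Gait cycle length in frames, >= 6.
#' @param phase Phase offset in cycles (0 to 1).
#' @param jitter_scale Per-frame articulation jitter: s.d. of the angle
#'   perturbation as a fraction of the swing amplitude.
#' @param flip_prob Per-frame pixel flip probability (segmentation
#'   noise), `[0, 0.2]`.
#' @param height_frac Figure height as a fraction of canvas height.
#' @param knee_ratio Shin swing as a fraction of the thigh swing.
#' @param arm_bend Forearm swing as a fraction of the upper-arm swing.
#' @param limb_width Limb half-thickness as a fraction of figure height.
#' @return Object of class `walker_params`.
#' @export
walker_params <- function(torso_width = 0.21, torso_length = 0.32,
                          head_radius = 0.07, leg_length = 0.50,
                          arm_length = 0.40, stride_amplitude = 28,
                          arm_amplitude = 22, cycle_frames = 14,
                          phase = 0, jitter_scale = 0.02,
                          flip_prob = 0.01, height_frac = 0.85,
                          knee_ratio = 0.4, arm_bend = 0.6,
                          limb_width = 0.024) {
  if (stride_amplitude < 0 || stride_amplitude > 60)
    stop("stride_amplitude must be in [0, 60] degrees")
  if (arm_amplitude < 0 || arm_amplitude > 60)
    stop("arm_amplitude must be in [0, 60] degrees")
  if (cycle_frames < 6) stop("cycle_frames must be >= 6")
  if (flip_prob < 0 || flip_prob > 0.2)
    stop("flip_prob must be in [0, 0.2]")
  structure(list(torso_width = torso_width, torso_length = torso_length,
                 head_radius = head_radius, leg_length = leg_length,
                 arm_length = arm_length, stride_amplitude = stride_amplitude,
                 arm_amplitude = arm_amplitude, cycle_frames = cycle_frames,
                 phase = phase, jitter_scale = jitter_scale,
                 flip_prob = flip_prob, height_frac = height_frac,
                 knee_ratio = knee_ratio, arm_bend = arm_bend,
                 limb_width = limb_width),
            class = "walker_params")
}

# thick line segment (capsule) rasterization over precomputed grids
.capsule <- function(xx, yy, p0, p1, r) {
  vx <- p1[1L] - p0[1L]; vy <- p1[2L] - p0[2L]
  L2 <- vx * vx + vy * vy
  if (L2 == 0) return((xx - p0[1L])^2 + (yy - p0[2L])^2 <= r * r)
  t <- ((xx - p0[1L]) * vx + (yy - p0[2L]) * vy) / L2
  t <- pmin(pmax(t, 0), 1)
  (xx - (p0[1L] + t * vx))^2 + (yy - (p0[2L] + t * vy))^2 <= r * r
}

#' Render one frame of the synthetic walker
#'
#' Deterministic given `(params, frame_index, canvas)`: the articulation
#' phase is `params$phase + frame_index / params$cycle_frames`, so a
#' frame one full cycle later is pixel-identical, and zero swing
#' amplitudes give a static figure.
#'
#' @param params A `walker_params`.
#' @param frame_index Integer frame number (0-based in the phase
#'   convention).
#' @param canvas `c(H, W)` canvas size in pixels.
#' @return Binary 0/1 matrix `H x W`.
#' @export
render_walker <- function(params, frame_index, canvas = c(128, 96)) {
  stopifnot(inherits(params, "walker_params"))
  H <- canvas[1L]; W <- canvas[2L]
  h <- params$height_frac * H
  ph <- 2 * pi * (params$phase + frame_index / params$cycle_frames)
  deg <- pi / 180
  y_top <- (H - h) / 2
  R <- params$head_radius * h
  y_neck <- y_top + 2 * R
  y_hip <- y_top + h * (1 - params$leg_length)
  x0 <- (W - 1) / 2
  leg <- params$leg_length * h
  arm <- params$arm_length * h
  lw <- params$limb_width * h

  th <- params$stride_amplitude * deg * sin(ph)      # thigh swing
  # arms counter-swing, lagging the legs slightly as in natural gait
  ar <- params$arm_amplitude * deg * sin(ph + pi + 2 * pi * 0.07)
  limb <- function(origin, a1, a2, l1, l2) {
    knee <- origin + c(sin(a1), cos(a1)) * l1
    foot <- knee + c(sin(a2), cos(a2)) * l2
    list(knee = knee, foot = foot)
  }
  # small lateral offset between the near and far limb (side view depth),
  # so crossing limbs never coincide exactly
  off <- 0.012 * h
  hipL <- c(x0 - off, y_hip); hipR <- c(x0 + off, y_hip)
  shL <- c(x0 + off, y_neck + 0.04 * h); shR <- c(x0 - off, y_neck + 0.04 * h)
  kn <- params$knee_ratio; ab <- params$arm_bend
  legL <- limb(hipL, th, th * kn, leg * 0.52, leg * 0.50)
  legR <- limb(hipR, -th, -th * kn, leg * 0.52, leg * 0.50)
  armL <- limb(shL, ar, ar * ab, arm * 0.52, arm * 0.50)
  armR <- limb(shR, -ar, -ar * ab, arm * 0.52, arm * 0.50)

  ext <- c(legL$foot, legR$foot, armL$foot, armR$foot)
  xs <- ext[c(1, 3, 5, 7)]
  if (min(xs) - lw < 0 || max(xs) + lw > W - 1 ||
      max(legL$foot[2L], legR$foot[2L]) + lw > H - 1)
    stop("walker figure exceeds the canvas; enlarge the canvas or reduce amplitudes")

  xx <- matrix(rep(0:(W - 1), each = H), H, W)       # x = column, 0-based
  yy <- matrix(rep(0:(H - 1), times = W), H, W)      # y = row
  mask <- (xx - x0)^2 + (yy - (y_top + R))^2 <= R * R            # head
  tc <- (y_neck + y_hip) / 2
  a <- params$torso_width * h / 2
  b <- (y_hip - y_neck) / 2 * 1.15
  mask <- mask | ((xx - x0)^2 / a^2 + (yy - tc)^2 / b^2 <= 1)    # torso
  for (lb in list(list(hipL, legL$knee, legL$foot),
                  list(hipR, legR$knee, legR$foot),
                  list(shL, armL$knee, armL$foot),
                  list(shR, armR$knee, armR$foot))) {
    mask <- mask | .capsule(xx, yy, lb[[1L]], lb[[2L]], lw)
    mask <- mask | .capsule(xx, yy, lb[[2L]], lb[[3L]], lw * 0.9)
  }
  mask * 1
}

#' Render a walking sequence with articulation jitter and pixel noise
#'
#' Frames are rendered at consecutive frame indices; each frame's swing
#' amplitudes are perturbed by Gaussian jitter (`jitter_scale`) and a
#' random fraction `flip_prob` of pixels is flipped, emulating
#' segmentation noise. Uses the current RNG stream; seed it (or use
#' [generate_population()]) for reproducibility.
#'
#' @param params A `walker_params`.
#' @param n_frames Number of frames.
#' @param canvas `c(H, W)`.
#' @param subject_id,sequence_id,view_angle Labels for the sequence.
#' @return A `gait_sequence`.
#' @export
render_sequence <- function(params, n_frames, canvas = c(128, 96),
                            subject_id = "unknown", sequence_id = "seq",
                            view_angle = 90) {
  stopifnot(inherits(params, "walker_params"), n_frames >= 1)
  frames <- vector("list", n_frames)
  for (j in seq_len(n_frames)) {
    p <- params
    if (params$jitter_scale > 0) {
      p$stride_amplitude <- max(0, min(60, params$stride_amplitude *
        (1 + stats::rnorm(1, 0, params$jitter_scale))))
      p$arm_amplitude <- max(0, min(60, params$arm_amplitude *
        (1 + stats::rnorm(1, 0, params$jitter_scale))))
    }
    m <- render_walker(p, j - 1L, canvas)
    if (params$flip_prob > 0) {
      flip <- stats::runif(length(m)) < params$flip_prob
      m[flip] <- 1 - m[flip]
    }
    frames[[j]] <- m
  }
  gait_sequence(frames, subject_id, sequence_id, view_angle)
}

#' Generate a reproducible synthetic walking population
#'
#' Draws one parameter set per subject from documented ranges (body
#' ratios, swing amplitudes, cadence), then renders `seqs_per_subject`
#' sequences per subject that share those parameters but differ in
#' phase offset, articulation jitter and pixel noise. Fully reproducible
#' from `seed`; the caller's RNG stream is left untouched.
#'
#' Subject parameters are drawn by a Latin-hypercube design: for each
#' parameter the range is split into `n_subjects` equal cells, the cells
#' are assigned to subjects in independent random permutations, and the
#' value is drawn uniformly within its cell. Every pair of subjects is
#' therefore guaranteed to be spread apart in every parameter, which is
#' what makes the population's subjects distinguishable by construction.
#' Ranges: torso width 0.15-0.28, torso length 0.28-0.36, head radius
#' 0.05-0.09, leg length 0.42-0.58, arm length 0.33-0.47, stride
#' amplitude 14-44 deg, arm amplitude 8-36 deg, body height 0.76-0.90
#' of the canvas, knee ratio 0.25-0.55, arm bend 0.40-0.80, limb
#' half-thickness 0.018-0.030, cycle length 12-17 frames (permuted
#' levels).
#'
#' @param n_subjects Number of subjects, >= 2.
#' @param seqs_per_subject Sequences per subject (default 2).
#' @param frames_per_seq Frames per sequence (default 40).
#' @param seed Integer seed (default 1).
#' @param canvas `c(H, W)` (default `c(128, 96)`).
#' @param flip_prob Pixel flip probability per frame (default 0.005).
#' @param jitter_scale Articulation jitter fraction (default 0.02).
#' @return List of `gait_sequence` of length
#'   `n_subjects * seqs_per_subject`, subjects labelled `"S01"`, ...
#' @export
generate_population <- function(n_subjects, seqs_per_subject = 2,
                                frames_per_seq = 40, seed = 1,
                                canvas = c(128, 96), flip_prob = 0.005,
                                jitter_scale = 0.02) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  .with_seed(seed, {
    # Latin-hypercube subject draws: one permuted cell per subject and
    # parameter, uniform within the cell
    lhs <- function(lo, hi) {
      cell <- (sample(n_subjects) - 1 + stats::runif(n_subjects)) / n_subjects
      lo + cell * (hi - lo)
    }
    draws <- list(torso_width = lhs(0.15, 0.28),
                  torso_length = lhs(0.28, 0.36),
                  head_radius = lhs(0.05, 0.09),
                  leg_length = lhs(0.42, 0.58),
                  arm_length = lhs(0.33, 0.47),
                  stride_amplitude = lhs(14, 44),
                  arm_amplitude = lhs(8, 36),
                  height_frac = lhs(0.76, 0.90),
                  knee_ratio = lhs(0.25, 0.55),
                  arm_bend = lhs(0.40, 0.80),
                  limb_width = lhs(0.018, 0.030),
                  cycle_frames = 12L + (sample(n_subjects) - 1L) %% 6L)
    out <- vector("list", n_subjects * seqs_per_subject)
    k <- 0L
    for (s in seq_len(n_subjects)) {
      base <- walker_params(
        torso_width = draws$torso_width[s],
        torso_length = draws$torso_length[s],
        head_radius = draws$head_radius[s],
        leg_length = draws$leg_length[s],
        arm_length = draws$arm_length[s],
        stride_amplitude = draws$stride_amplitude[s],
        arm_amplitude = draws$arm_amplitude[s],
        height_frac = draws$height_frac[s],
        knee_ratio = draws$knee_ratio[s],
        arm_bend = draws$arm_bend[s],
        limb_width = draws$limb_width[s],
        cycle_frames = draws$cycle_frames[s],
        jitter_scale = jitter_scale, flip_prob = flip_prob)
      sid <- sprintf("S%02d", s)
      for (q in seq_len(seqs_per_subject)) {
        p <- base
        p$phase <- stats::runif(1)
        k <- k + 1L
        out[[k]] <- render_sequence(p, frames_per_seq, canvas,
                                    subject_id = sid,
                                    sequence_id = sprintf("seq%02d", q))
      }
    }
    out
  })
}
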