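## Stack-of-stars trajectory construction, density compensation and shot
## duration accounting.

#' Golden-angle spoke schedule
#'
#' Returns the in-plane spoke angles of a radial acquisition. In `continuous`
#' mode the global spoke index k (0-based, running across frames) receives
#' angle `(k * pi * (sqrt(5) - 1) / 2) mod pi`, the golden-angle increment of
#' about 1.94161 rad = 111.246 degrees (180 degrees divided by the golden
#' ratio), so that any consecutive subset of spokes covers [0, pi)
#' near-uniformly. In `per_frame` mode the golden sequence restarts at every
#' frame, giving identical spoke sets in each frame.
#'
#' @param n_frames number of dynamic frames (>= 1).
#' @param n_spokes_per_frame radial spokes acquired per frame (>= 1).
#' @param mode `"continuous"` (default) or `"per_frame"`.
#' @return numeric matrix `[n_frames, n_spokes_per_frame]` of angles in
#'   radians, all in `[0, pi)`.
#' @export
#' @examples
#' a <- golden_angle_schedule(2, 3)
#' diff(a[1, 1:2])  # ~1.9416 rad, the golden angle
golden_angle_schedule <- function(n_frames, n_spokes_per_frame,
                                  mode = c("continuous", "per_frame")) {
  mode <- match.arg(mode)
  if (n_frames < 1 || n_spokes_per_frame < 1)
    stop_invalid("n_frames and n_spokes_per_frame must both be >= 1")
  ga <- pi * (sqrt(5) - 1) / 2   # 111.246 degrees
  if (mode == "continuous") {
    k <- seq_len(n_frames * n_spokes_per_frame) - 1
    matrix((k * ga) %% pi, nrow = n_frames, ncol = n_spokes_per_frame,
           byrow = TRUE)
  } else {
    k <- seq_len(n_spokes_per_frame) - 1
    matrix(rep((k * ga) %% pi, each = n_frames),
           nrow = n_frames, ncol = n_spokes_per_frame)
  }
}

#' Build a stack-of-stars sampling pattern
#'
#' Constructs the full geometric description of a stack-of-stars acquisition:
#' radial spokes in-plane (angle schedule), Cartesian partition encoding along
#' kz, readout sampling and undersampling structure. Spokes are aligned across
#' partitions (not rotated between kz steps) so the kz axis factorises into a
#' separable Cartesian FFT. The default partition ordering is centric (centre
#' of k-space first), so that the central partitions coincide with the
#' cardiac-phase target of the shot (the end-systolic pause).
#'
#' @param n_readout samples per spoke; even, spans `[-k_max, k_max)` at
#'   spacing `2 * k_max / n_readout`.
#' @param n_spokes_per_frame spokes per dynamic frame.
#' @param n_frames number of frames (one frame per cardiac cycle).
#' @param n_partitions Cartesian kz partitions (even, or 1 for 2D radial).
#' @param angle_mode `"continuous"` golden angle across the whole series
#'   (default), `"per_frame"` golden angle restarted each frame, or
#'   `"linear"` uniform spacing `pi / n_spokes_per_frame` repeated each frame.
#' @param kz_mode `"centric"` (centre partition first, then outward,
#'   lower index first on ties) or `"linear"` (0, 1, ..., in order).
#' @param k_max normalised spatial-frequency bound in cycles per sample
#'   spacing (0.5 = Nyquist of the reconstruction grid).
#' @param readout_oversampling readout oversampling ratio (>= 1); with the
#'   default 2 a spoke holds twice as many samples as the image matrix, at
#'   half the radial spacing.
#' @return an object of class `sampling_pattern`.
#' @export
build_pattern <- function(n_readout = 128L,
                          n_spokes_per_frame = 10L,
                          n_frames = 32L,
                          n_partitions = 16L,
                          angle_mode = c("continuous", "per_frame", "linear"),
                          kz_mode = c("centric", "linear"),
                          k_max = 0.5,
                          readout_oversampling = 2) {
  angle_mode <- match.arg(angle_mode)
  kz_mode <- match.arg(kz_mode)
  if (n_readout < 2 || n_readout %% 2L != 0L)
    stop_invalid("n_readout must be a positive even integer, got %s",
                 format(n_readout))
  if (n_spokes_per_frame < 1 || n_frames < 1)
    stop_invalid("spoke and frame counts must be >= 1")
  if (n_partitions < 1 || (n_partitions > 1 && n_partitions %% 2L != 0L))
    stop_invalid("n_partitions must be 1 or a positive even integer")
  if (!is.finite(k_max) || k_max <= 0 || k_max > 0.5)
    stop_invalid("k_max must lie in (0, 0.5]")
  if (readout_oversampling < 1)
    stop_invalid("readout_oversampling must be >= 1")

  angle_schedule <- switch(angle_mode,
    continuous = golden_angle_schedule(n_frames, n_spokes_per_frame,
                                       "continuous"),
    per_frame = golden_angle_schedule(n_frames, n_spokes_per_frame,
                                      "per_frame"),
    linear = matrix(rep((seq_len(n_spokes_per_frame) - 1) *
                          pi / n_spokes_per_frame, each = n_frames),
                    nrow = n_frames, ncol = n_spokes_per_frame))

  p <- seq_len(n_partitions) - 1L
  kz_order <- switch(kz_mode,
    linear = p,
    centric = p[order(abs(p - n_partitions %/% 2L), p)])

  structure(list(
    n_readout = as.integer(n_readout),
    n_spokes_per_frame = as.integer(n_spokes_per_frame),
    n_frames = as.integer(n_frames),
    n_partitions = as.integer(n_partitions),
    angle_schedule = angle_schedule,
    kz_order = as.integer(kz_order),
    k_max = k_max,
    readout_oversampling = readout_oversampling,
    angle_mode = angle_mode,
    kz_mode = kz_mode,
    cache = new.env(parent = emptyenv())
  ), class = "sampling_pattern")
}

#' @export
print.sampling_pattern <- function(x, ...) {
  cat(sprintf(
    "stack-of-stars sampling pattern\n  %d frames x %d spokes x %d readout, %d kz partitions\n  angle mode: %s; kz order: %s; k_max = %g; readout oversampling = %g\n",
    x$n_frames, x$n_spokes_per_frame, x$n_readout, x$n_partitions,
    x$angle_mode, x$kz_mode, x$k_max, x$readout_oversampling))
  invisible(x)
}

## radial k-space offsets along one spoke, in cycles per sample spacing
.readout_kr <- function(pattern) {
  dk <- 2 * pattern$k_max / pattern$n_readout
  ((seq_len(pattern$n_readout) - 1) - pattern$n_readout / 2) * dk
}

## (kx, ky) for every sample of one frame, readout fastest
.frame_kcoords <- function(pattern, frame) {
  kr <- .readout_kr(pattern)
  th <- pattern$angle_schedule[frame, ]
  list(kx = as.vector(outer(kr, cos(th))),
       ky = as.vector(outer(kr, sin(th))))
}

#' Ramp density-compensation weights
#'
#' Per-sample weights correcting the 1/|k| oversampling of the k-space centre
#' by radial trajectories: `w ~ |k|` for off-centre samples, while the DC
#' sample of each spoke receives the continuum ramp limit over the central
#' cell, `dk / 8` (integrating |k| over the half-cell `[-dk/2, dk/2]` shared
#' by the spoke gives `dk^2/8` per unit spacing; on ties with the ramp this
#' analytic limit wins). Weights are constant across partitions and frames
#' and are normalised so that their total over one frame's samples equals the
#' area of the sampled k-space disc times the number of partitions,
#' `pi * k_max^2 * n_partitions`, which makes the density-compensated adjoint
#' an approximate inverse (see [gridding_recon()]).
#'
#' @param pattern a `sampling_pattern`.
#' @return numeric array `[n_readout, n_spokes_per_frame, n_partitions]` of
#'   strictly positive weights.
#' @export
density_compensation <- function(pattern) {
  stopifnot(inherits(pattern, "sampling_pattern"))
  kr <- .readout_kr(pattern)
  dk <- 2 * pattern$k_max / pattern$n_readout
  w <- abs(kr)
  w[pattern$n_readout / 2 + 1] <- dk / 8
  w <- array(w, c(pattern$n_readout, pattern$n_spokes_per_frame,
                  pattern$n_partitions))
  target <- pi * pattern$k_max^2 * pattern$n_partitions
  w * (target / sum(w))
}

#' Shot duration of one cardiac cycle's acquisition
#'
#' The shot is the contiguous data-acquisition window within one cardiac
#' cycle: all spokes of one frame across all encoded partitions. Its duration
#' is the repetition time multiplied by the number of k-space lines per shot,
#' `n_spokes_per_frame * length(kz_order)`. The default pattern (10 spokes,
#' 16 partitions) at TR = 1.175 ms yields the 188 ms target of the method's
#' sequence optimisation.
#'
#' @param pattern a `sampling_pattern`.
#' @param tr_ms repetition time of one k-space line, in milliseconds (> 0).
#' @return shot duration in milliseconds.
#' @export
shot_duration <- function(pattern, tr_ms) {
  stopifnot(inherits(pattern, "sampling_pattern"))
  if (!is.finite(tr_ms) || tr_ms <= 0)
    stop_invalid("tr_ms must be a positive number")
  tr_ms * pattern$n_spokes_per_frame * length(pattern$kz_order)
}
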