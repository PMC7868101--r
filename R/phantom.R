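## Dynamic first-pass perfusion phantom: tracer kinetics, signal model,
## left-ventricular geometry, respiratory motion and ECG trigger simulation.

#' Dynamic volume container
#'
#' Complex 3D+time image stack with voxel geometry and frame timing. One
#' volume per cardiac cycle: every slice of a frame shares the same cardiac
#' phase.
#'
#' @param data complex (or numeric) array `[nx, ny, nz, n_frames]`.
#' @param voxel_mm voxel size in mm, length 3 (through-plane last).
#' @param frame_times acquisition time of each frame in seconds, strictly
#'   increasing.
#' @param source provenance tag: `"phantom"`, `"gridding"`, `"stcr"` or
#'   `"file"`.
#' @return object of class `dynamic_volume`.
#' @export
dynamic_volume <- function(data, voxel_mm, frame_times,
                           source = c("phantom", "gridding", "stcr", "file")) {
  source <- match.arg(source)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop_invalid("dynamic volume data must be a 4D [x, y, z, frame] array")
  if (!all(is.finite(Re(data))) || !all(is.finite(Im(data))))
    stop_invalid("dynamic volume values must all be finite")
  if (length(frame_times) != dim(data)[4])
    stop_invalid("frame_times length must match the number of frames")
  if (length(frame_times) > 1 && any(diff(frame_times) <= 0))
    stop_invalid("frame times must be strictly increasing")
  structure(list(
    data = if (is.complex(data)) data else data + 0i,
    voxel_mm = as.numeric(voxel_mm),
    frame_times = as.numeric(frame_times),
    source = source
  ), class = "dynamic_volume")
}

#' @export
print.dynamic_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "dynamic volume [%s]: %d x %d x %d voxels, %d frames, voxel %s mm\n",
    x$source, d[1], d[2], d[3], d[4],
    paste(format(x$voxel_mm), collapse = " x ")))
  invisible(x)
}

#' Phantom specification
#'
#' Generative description of a first-pass perfusion acquisition: grid and
#' left-ventricular geometry, arterial-input and one-compartment tissue
#' kinetics, inducible hypoperfusion defects, sinusoidal respiratory motion
#' and ECG triggering. All randomness derives from `seed` (component streams
#' use fixed documented offsets from it).
#'
#' The kinetic defaults are chosen to satisfy first-pass orderings (bolus
#' peaks in the blood pool before the myocardium; enhancement strongly
#' T1-weighted) rather than to reproduce any patient's quantitative values:
#' peak arterial gadolinium ~4 mM for a 0.1 mmol/kg bolus, stress-level
#' `Ktrans` 0.035 /s, gadobutrol relaxivity 4.5 /(mM s) at 3 T, saturation
#' delay 100 ms.
#'
#' @param grid voxel counts `c(nx, ny, nz)`; in-plane extents even.
#' @param voxel_mm voxel size in mm (default 3 x 3 in-plane, 5 through-plane).
#' @param lv list: `endo_mm`, `epi_mm` (endocardial/epicardial radii),
#'   `long_axis_mm` (base-apex extent), `center_mm` (length 3).
#' @param aif gamma-variate arterial input: amplitude `A` (mM), delay `t0`
#'   (s), shape `alpha`, scale `beta` (s).
#' @param tissue named list of regions `bloodpool`, `myocardium`,
#'   `background`, each holding `Ktrans` (1/s), `kep` (1/s), `R1_0` (1/s),
#'   `r1` (1/(mM s)), `M0`.
#' @param defects list of defects, each
#'   `list(angle_deg = c(from, to), partitions = c(first, last),
#'   transmural = f, flow_reduction = r)` with transmural fraction in (0, 1]
#'   measured from the endocardium and flow reduction in \[0, 1).
#' @param motion respiratory motion: `amplitude_mm` (per axis, length 3) and
#'   `period_s`.
#' @param trigger `rr_s` (RR interval), `jitter_sd_s`, `mistrigger_prob`,
#'   `mistrigger_shift_mm` (geometry jolt of a mis-triggered frame).
#' @param sat_delay_s saturation-recovery delay TS in seconds.
#' @param n_frames number of cardiac cycles simulated.
#' @param seed integer seed for all phantom randomness.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(64L, 64L, 16L),
                         voxel_mm = c(3, 3, 5),
                         lv = list(endo_mm = 17, epi_mm = 30,
                                   long_axis_mm = 80,
                                   center_mm = c(0, 0, 0)),
                         aif = list(A = 4, t0 = 4, alpha = 2.5, beta = 1.5),
                         tissue = list(
                           bloodpool = list(Ktrans = 0, kep = 0,
                                            R1_0 = 0.55, r1 = 4.5, M0 = 1),
                           myocardium = list(Ktrans = 0.035, kep = 0.15,
                                             R1_0 = 0.85, r1 = 4.5, M0 = 1),
                           background = list(Ktrans = 0, kep = 0,
                                             R1_0 = 0.9, r1 = 4.5, M0 = 1)),
                         defects = list(),
                         motion = list(amplitude_mm = c(1, 2, 5),
                                       period_s = 4),
                         trigger = list(rr_s = 1, jitter_sd_s = 0.01,
                                        mistrigger_prob = 0.03,
                                        mistrigger_shift_mm = 6),
                         sat_delay_s = 0.1,
                         n_frames = 32L,
                         seed = 1L) {
  if (length(grid) != 3L || any(grid < 1))
    stop_invalid("grid must be three positive voxel counts")
  if (grid[1] %% 2L != 0L || grid[2] %% 2L != 0L)
    stop_invalid("in-plane grid extents must be even")
  if (lv$endo_mm >= lv$epi_mm)
    stop_invalid("endocardial radius must be smaller than epicardial radius")
  if (n_frames < 1) stop_invalid("n_frames must be >= 1")
  if (aif$alpha <= 0 || aif$beta <= 0)
    stop_invalid("aif alpha and beta must be positive")
  for (nm in names(tissue)) {
    tt <- tissue[[nm]]
    if (any(unlist(tt[c("Ktrans", "kep", "R1_0", "r1")]) < 0))
      stop_invalid("tissue rate constants must be nonnegative (%s)", nm)
  }
  p <- trigger$mistrigger_prob
  if (!is.finite(p) || p < 0 || p > 1)
    stop_invalid("mistrigger probability must lie in [0, 1]")
  for (i in seq_along(defects)) {
    d <- defects[[i]]
    if (is.null(d$transmural) || d$transmural <= 0 || d$transmural > 1)
      stop_invalid("defect %d: transmural fraction must lie in (0, 1]", i)
    if (is.null(d$flow_reduction) || d$flow_reduction < 0 ||
        d$flow_reduction >= 1)
      stop_invalid("defect %d: flow_reduction must lie in [0, 1)", i)
    if (is.null(d$partitions) || d$partitions[1] < 1 ||
        d$partitions[2] > grid[3] || d$partitions[1] > d$partitions[2])
      stop_invalid("defect %d: partition span exceeds the slab geometry", i)
    if (is.null(d$angle_deg) || length(d$angle_deg) != 2L)
      stop_invalid("defect %d: angular span must be c(from, to) degrees", i)
  }
  structure(list(grid = as.integer(grid), voxel_mm = as.numeric(voxel_mm),
                 lv = lv, aif = aif, tissue = tissue, defects = defects,
                 motion = motion, trigger = trigger,
                 sat_delay_s = sat_delay_s,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Gamma-variate arterial input function
#'
#' Peak-normalised gamma-variate bolus model of the arterial gadolinium
#' concentration: `c(t) = A ((t - t0)/(alpha beta))^alpha
#' exp(alpha - (t - t0)/beta)` for `t > t0`, zero before the bolus arrives.
#' The peak sits at `t = t0 + alpha * beta` with value `A`.
#'
#' @param times sample times in seconds.
#' @param A peak concentration (mM).
#' @param t0 bolus arrival delay (s).
#' @param alpha shape parameter (> 0).
#' @param beta scale parameter in seconds (> 0).
#' @return concentration curve in mM, same length as `times`.
#' @export
aif_curve <- function(times, A = 4, t0 = 4, alpha = 2.5, beta = 1.5) {
  if (alpha <= 0 || beta <= 0)
    stop_invalid("alpha and beta must be positive")
  dt <- times - t0
  out <- numeric(length(times))
  up <- which(dt > 0)
  out[up] <- A * (dt[up] / (alpha * beta))^alpha * exp(alpha - dt[up] / beta)
  out
}

#' One-compartment tissue concentration
#'
#' Convolves an arterial input curve with the one-compartment residue
#' `Ktrans * exp(-kep * t)`:
#' `C(t) = Ktrans * integral_0^t aif(tau) exp(-kep (t - tau)) dtau`,
#' discretised by trapezoidal quadrature (evaluated recursively, which is
#' algebraically identical to the direct trapezoidal convolution).
#'
#' @param aif arterial concentration sampled at uniform spacing `dt`.
#' @param Ktrans transfer constant (1/s, >= 0).
#' @param kep efflux constant (1/s, >= 0).
#' @param dt sample spacing in seconds (> 0).
#' @return tissue concentration curve (mM), same length as `aif`.
#' @export
tissue_concentration <- function(aif, Ktrans, kep, dt) {
  if (dt <= 0) stop_invalid("dt must be positive")
  if (Ktrans < 0 || kep < 0)
    stop_invalid("Ktrans and kep must be nonnegative")
  n <- length(aif)
  C <- numeric(n)
  if (n < 2) return(C)
  decay <- exp(-kep * dt)
  for (i in 2:n) {
    C[i] <- C[i - 1] * decay +
      Ktrans * dt / 2 * (aif[i - 1] * decay + aif[i])
  }
  C
}

#' Saturation-recovery signal model
#'
#' T1-weighted signal intensity after a saturation preparation with delay
#' `TS`: `S = M0 (1 - exp(-TS (R1_0 + r1 C)))`, monotone increasing in the
#' gadolinium concentration `C` and saturating at `M0`.
#'
#' @param C gadolinium concentration (mM).
#' @param M0 equilibrium signal.
#' @param R1_0 native longitudinal relaxation rate (1/s).
#' @param r1 contrast-agent relaxivity (1/(mM s)).
#' @param TS saturation delay in seconds (> 0).
#' @return signal intensity, same shape as `C`.
#' @export
signal_from_concentration <- function(C, M0, R1_0, r1, TS) {
  if (TS <= 0) stop_invalid("TS must be positive")
  M0 * (1 - exp(-TS * (R1_0 + r1 * C)))
}

#' Simulate ECG trigger timing
#'
#' Each frame's acquisition time is offset from its nominal R-wave by
#' Normal(0, jitter sd) trigger jitter. With probability `mistrigger_prob`
#' a frame is flagged as mis-triggered and its offset is instead drawn from a
#' wide uniform distribution over half the RR interval on either side,
#' emulating R-wave detection failures that place the shot at the wrong
#' cardiac phase. Reproducible under the spec seed (trigger stream at
#' `seed + 1`).
#'
#' @param spec a `phantom_spec`.
#' @return list with `offset_s` (per-frame trigger offset, seconds) and
#'   `mistriggered` (logical flags).
#' @export
simulate_triggers <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  tr <- spec$trigger
  n <- spec$n_frames
  with_seed(spec$seed + 1L, {
    flags <- stats::runif(n) < tr$mistrigger_prob
    off <- stats::rnorm(n, 0, tr$jitter_sd_s)
    if (any(flags))
      off[flags] <- stats::runif(sum(flags), -tr$rr_s / 2, tr$rr_s / 2)
    list(offset_s = off, mistriggered = flags)
  })
}

## mm coordinates of voxel centres; DC voxel of the centred DFT (0-based
## index n/2) sits at coordinate 0.
.grid_coords_mm <- function(n, voxel) ((seq_len(n) - 1) - n / 2) * voxel

## Ellipsoidal-shell radius scale per slice: full radius over the basal half
## of the long axis, ellipsoidal taper towards the apex, zero outside.
.lv_radius_scale <- function(z_mm, center_z, long_axis_mm) {
  u <- (z_mm - center_z) / (long_axis_mm / 2)
  s <- numeric(length(u))
  s[u <= 0 & u >= -1] <- 1
  ap <- u > 0 & u < 1
  s[ap] <- sqrt(1 - u[ap]^2)
  s
}

## Rasterise labels for one frame: 0 background, 1 bloodpool, 2 myocardium,
## 2 + k defect k. Geometry is analytic and re-rendered under the given
## translation; no resampling.
.rasterize_lv <- function(spec, shift_mm = c(0, 0, 0)) {
  g <- spec$grid
  cx <- spec$lv$center_mm[1] + shift_mm[1]
  cy <- spec$lv$center_mm[2] + shift_mm[2]
  cz <- spec$lv$center_mm[3] + shift_mm[3]
  x <- .grid_coords_mm(g[1], spec$voxel_mm[1]) - cx
  y <- .grid_coords_mm(g[2], spec$voxel_mm[2]) - cy
  z <- .grid_coords_mm(g[3], spec$voxel_mm[3])
  r2 <- outer(x^2, y^2, `+`)
  th <- (atan2(outer(rep(1, g[1]), y), outer(x, rep(1, g[2]))) * 180 / pi) %% 360
  s <- .lv_radius_scale(z, cz, spec$lv$long_axis_mm)
  labels <- array(0L, g)
  for (iz in seq_len(g[3])) {
    if (s[iz] <= 0) next
    endo <- spec$lv$endo_mm * s[iz]
    epi <- spec$lv$epi_mm * s[iz]
    r <- sqrt(r2)
    blood <- r <= endo
    myo <- r > endo & r <= epi
    lab <- matrix(0L, g[1], g[2])
    lab[blood] <- 1L
    lab[myo] <- 2L
    for (k in seq_along(spec$defects)) {
      d <- spec$defects[[k]]
      if (iz < d$partitions[1] || iz > d$partitions[2]) next
      a0 <- d$angle_deg[1] %% 360; a1 <- d$angle_deg[2] %% 360
      in_ang <- if (a0 <= a1) th >= a0 & th < a1 else th >= a0 | th < a1
      rmax <- endo + d$transmural * (epi - endo)
      lab[myo & in_ang & r <= rmax] <- 2L + k
    }
    labels[, , iz] <- lab
  }
  labels
}

## body ellipse mask (static torso) for background intensity
.body_mask <- function(spec) {
  g <- spec$grid
  x <- .grid_coords_mm(g[1], spec$voxel_mm[1])
  y <- .grid_coords_mm(g[2], spec$voxel_mm[2])
  rx <- 0.46 * g[1] * spec$voxel_mm[1]
  ry <- 0.40 * g[2] * spec$voxel_mm[2]
  el <- outer((x / rx)^2, (y / ry)^2, `+`) <= 1
  array(el, g)
}

#' Render the dynamic phantom
#'
#' Rasterises an ellipsoidal-shell left ventricle on the voxel grid and
#' evolves it through the first pass of a contrast bolus: the blood pool
#' follows the arterial input function, the myocardium follows the
#' one-compartment tissue model, and defect wedges use
#' `Ktrans * (1 - flow_reduction)` over their angular, partition and
#' transmural extent. Each frame is rigidly translated by a sinusoidal
#' respiratory trace (one position per cardiac cycle); mis-triggered frames
#' receive an additional geometry shift proportional to their trigger offset.
#' Geometry is re-rendered analytically per frame - never interpolated - so
#' reconstruction tests are not confounded by resampling blur.
#'
#' @param spec a `phantom_spec`.
#' @return list with `volume` (a `dynamic_volume`, provenance `"phantom"`)
#'   and `truth` (a `ground_truth`: per-frame label volumes that partition
#'   the grid, rigid shifts in mm, trigger offsets and flags, and the
#'   per-region concentration curves in mM).
#' @export
render_dynamic_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  nf <- spec$n_frames
  rr <- spec$trigger$rr_s
  tf <- (seq_len(nf) - 1) * rr
  tri <- simulate_triggers(spec)
  t_acq <- tf + tri$offset_s

  ## kinetics on a fine grid, sampled at the acquisition times
  dt <- 0.02
  t_fine <- seq(0, max(t_acq) + rr + dt, by = dt)
  cb_fine <- aif_curve(t_fine, spec$aif$A, spec$aif$t0, spec$aif$alpha,
                       spec$aif$beta)
  myo <- spec$tissue$myocardium
  cm_fine <- tissue_concentration(cb_fine, myo$Ktrans, myo$kep, dt)
  conc <- list(bloodpool = stats::approx(t_fine, cb_fine, t_acq,
                                         rule = 2)$y,
               myocardium = stats::approx(t_fine, cm_fine, t_acq,
                                          rule = 2)$y)
  for (k in seq_along(spec$defects)) {
    fr <- spec$defects[[k]]$flow_reduction
    cd <- tissue_concentration(cb_fine, myo$Ktrans * (1 - fr), myo$kep, dt)
    conc[[paste0("defect_", k)]] <- stats::approx(t_fine, cd, t_acq,
                                                  rule = 2)$y
  }

  TS <- spec$sat_delay_s
  sig <- cbind(
    background = rep(signal_from_concentration(
      0, spec$tissue$background$M0, spec$tissue$background$R1_0,
      spec$tissue$background$r1, TS), nf),
    bloodpool = signal_from_concentration(
      conc$bloodpool, spec$tissue$bloodpool$M0, spec$tissue$bloodpool$R1_0,
      spec$tissue$bloodpool$r1, TS),
    myocardium = signal_from_concentration(
      conc$myocardium, myo$M0, myo$R1_0, myo$r1, TS))
  for (k in seq_along(spec$defects))
    sig <- cbind(sig, signal_from_concentration(
      conc[[paste0("defect_", k)]], myo$M0, myo$R1_0, myo$r1, TS))

  amp <- spec$motion$amplitude_mm
  shifts <- cbind(amp[1] * sin(2 * pi * tf / spec$motion$period_s),
                  amp[2] * sin(2 * pi * tf / spec$motion$period_s),
                  amp[3] * sin(2 * pi * tf / spec$motion$period_s))
  extra <- spec$trigger$mistrigger_shift_mm *
    tri$offset_s / (rr / 2) * tri$mistriggered
  shifts[, 2] <- shifts[, 2] + extra

  body <- .body_mask(spec)
  vol <- array(0 + 0i, c(g, nf))
  labels <- array(0L, c(g, nf))
  bg <- sig[1, "background"]
  for (f in seq_len(nf)) {
    lab <- .rasterize_lv(spec, shifts[f, ])
    frame <- array(0, g)
    frame[body] <- bg
    frame[lab == 1L] <- sig[f, "bloodpool"]
    frame[lab == 2L] <- sig[f, "myocardium"]
    for (k in seq_along(spec$defects))
      frame[lab == 2L + k] <- sig[f, 3L + k]
    vol[, , , f] <- frame
    labels[, , , f] <- lab
  }

  curves <- data.frame(time = t_acq, aif = conc$bloodpool,
                       myocardium = conc$myocardium)
  for (k in seq_along(spec$defects))
    curves[[paste0("defect_", k)]] <- conc[[paste0("defect_", k)]]

  truth <- structure(list(
    labels = labels,
    label_levels = c("background", "bloodpool", "myocardium",
                     if (length(spec$defects))
                       paste0("defect-", seq_along(spec$defects))),
    shifts_mm = shifts,
    trigger_offset_s = tri$offset_s,
    mistriggered = tri$mistriggered,
    curves = curves,
    spec = spec
  ), class = "ground_truth")

  list(volume = dynamic_volume(vol, spec$voxel_mm, tf, "phantom"),
       truth = truth)
}
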