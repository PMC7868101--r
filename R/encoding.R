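## Multicoil stack-of-stars encoding: forward (type-2) and adjoint (type-1)
## nonuniform Fourier operators with two interchangeable backends - an exact
## direct-summation DFT (small-grid oracle) and Kaiser-Bessel gridding.

.KB_OS <- 2L        # image-domain oversampling of the gridding backend
.KB_WIDTH <- 8L     # kernel width in oversampled grid cells

.kb_beta <- function(w, os) pi * sqrt((w / os)^2 * (os - 0.5)^2 - 0.8)

.kb_kernel <- function(t, w, beta) {
  v <- numeric(length(t))
  inside <- abs(t) < w / 2
  v[inside] <- besselI(beta * sqrt(1 - (2 * t[inside] / w)^2), 0)
  v
}

## Deapodisation profile a(x) = FT of the kernel at x/G, by Simpson quadrature
.kb_deapod <- function(N, G, w, beta) {
  nt <- 513L
  tg <- seq(-w / 2, w / 2, length.out = nt)
  h <- tg[2] - tg[1]
  sw <- c(1, rep(c(4, 2), (nt - 3) / 2), 4, 1) * h / 3
  phi <- .kb_kernel(tg, w, beta)
  x <- (seq_len(N) - 1) - N / 2
  as.vector(cos(2 * pi * outer(x / G, tg)) %*% (sw * phi))
}

## Sparse interpolation matrices (one per frame) from the oversampled
## Cartesian spectrum to the frame's radial samples, plus the separable
## deapodisation image. The fftshift permutations of the oversampled grid
## are folded into the sparse column indices and the pad indices, so the
## per-frame transform is pad -> plain FFT -> sparse multiply with no
## explicit index shuffles. Cached on the pattern.
.nufft_plan <- function(pattern, nx, ny) {
  key <- sprintf("nufft_%d_%d", nx, ny)
  cached <- pattern$cache[[key]]
  if (!is.null(cached)) return(cached)
  if (nx != ny || nx %% 2L != 0L)
    stop_invalid("gridding backend requires a square even in-plane grid")
  G <- .KB_OS * nx
  w <- .KB_WIDTH
  beta <- .kb_beta(w, .KB_OS)
  a <- .kb_deapod(nx, G, w, beta)
  deapod <- outer(a, a)
  sw <- .swap(G)          # centred bin i lives at unswapped bin sw[i]
  off <- seq(-(w %/% 2 - 1L), w %/% 2)
  nf <- pattern$n_frames
  kr <- .readout_kr(pattern)
  th <- pattern$angle_schedule
  ## samples of all frames jointly, readout fastest, then spoke, then frame
  kx <- as.vector(outer(kr, as.vector(t(th)), function(r, a) r * cos(a)))
  ky <- as.vector(outer(kr, as.vector(t(th)), function(r, a) r * sin(a)))
  ns_frame <- pattern$n_readout * pattern$n_spokes_per_frame
  u <- kx * G + G / 2
  v <- ky * G + G / 2
  fu <- floor(u); fv <- floor(v)
  wu <- vapply(off, function(o) .kb_kernel(u - (fu + o), w, beta),
               numeric(length(u)))
  wv <- vapply(off, function(o) .kb_kernel(v - (fv + o), w, beta),
               numeric(length(v)))
  fid <- rep(seq_len(nf), each = ns_frame)
  sid <- rep(seq_len(ns_frame), nf)
  trip_i <- trip_j <- trip_x <- trip_f <- vector("list", length(off)^2)
  n <- 0L
  for (o1 in seq_along(off)) for (o2 in seq_along(off)) {
    wt <- wu[, o1] * wv[, o2]
    keep <- wt > 0
    if (!any(keep)) next
    n <- n + 1L
    g1 <- (fu[keep] + off[o1]) %% G
    g2 <- (fv[keep] + off[o2]) %% G
    trip_i[[n]] <- sid[keep]
    trip_j[[n]] <- (sw[g1 + 1L] - 1L) + G * (sw[g2 + 1L] - 1L) + 1L
    trip_x[[n]] <- wt[keep]
    trip_f[[n]] <- fid[keep]
  }
  ti <- unlist(trip_i[seq_len(n)]); tj <- unlist(trip_j[seq_len(n)])
  tx <- unlist(trip_x[seq_len(n)]); tf <- unlist(trip_f[seq_len(n)])
  interp <- interp_t <- vector("list", nf)
  for (f in seq_len(nf)) {
    sel <- tf == f
    interp[[f]] <- Matrix::sparseMatrix(i = ti[sel], j = tj[sel],
                                        x = tx[sel],
                                        dims = c(ns_frame, G * G))
    interp_t[[f]] <- Matrix::t(interp[[f]])
  }
  ## centred pad positions, pre-shuffled for the plain FFT
  cx <- (G / 2 - nx / 2 + 1):(G / 2 + nx / 2)
  cy <- (G / 2 - ny / 2 + 1):(G / 2 + ny / 2)
  plan <- list(G = G, deapod = deapod, interp = interp,
               interp_t = interp_t, pad_x = sw[cx], pad_y = sw[cy])
  pattern$cache[[key]] <- plan
  plan
}

## Direct-summation DFT matrices, one per frame (oracle backend; small grids)
.dft_plan <- function(pattern, nx, ny) {
  key <- sprintf("dft_%d_%d", nx, ny)
  cached <- pattern$cache[[key]]
  if (!is.null(cached)) return(cached)
  if (nx * ny > 2048L)
    stop_invalid(
      "the direct DFT backend is an oracle for in-plane grids <= 2048 pixels; use backend = 'nufft'")
  xc <- (seq_len(nx) - 1) - nx / 2
  yc <- (seq_len(ny) - 1) - ny / 2
  xg <- rep(xc, times = ny)
  yg <- rep(yc, each = nx)
  mats <- vector("list", pattern$n_frames)
  for (f in seq_len(pattern$n_frames)) {
    kc <- .frame_kcoords(pattern, f)
    mats[[f]] <- exp(-2i * pi * (outer(kc$kx, xg) + outer(kc$ky, yg)))
  }
  pattern$cache[[key]] <- mats
  mats
}

## sparse real matrix times complex dense matrix
.sp_cmult <- function(S, M) {
  as.matrix(S %*% Re(M)) + 1i * as.matrix(S %*% Im(M))
}

#' Simulate smooth coil sensitivity maps
#'
#' Places Gaussian sensitivity bumps around the field of view with smooth
#' phase variation and a mild through-plane modulation, emulating a receive
#' array. A single coil yields the uniform (all-ones) map. The root sum of
#' squares of the maps is strictly positive over the whole grid. Coil maps
#' are treated as known inputs to reconstruction; no self-calibration.
#'
#' @param grid voxel counts `c(nx, ny, nz)`.
#' @param n_coils number of receive coils (>= 1).
#' @param seed integer seed (maps are deterministic given the seed).
#' @return complex array `[nx, ny, nz, n_coils]` of class `coil_profile`.
#' @export
simulate_coils <- function(grid, n_coils, seed = 1L) {
  if (n_coils < 1) stop_invalid("n_coils must be >= 1")
  g <- as.integer(grid)
  if (n_coils == 1L)
    return(structure(array(1 + 0i, c(g, 1L)), class = "coil_profile"))
  maps <- array(0 + 0i, c(g, n_coils))
  x <- (seq_len(g[1]) - 1) - g[1] / 2
  y <- (seq_len(g[2]) - 1) - g[2] / 2
  z <- seq_len(g[3]) - (g[3] + 1) / 2
  R <- 0.55 * max(g[1], g[2])
  sigma <- 0.45 * max(g[1], g[2])
  with_seed(seed, {
    for (cc in seq_len(n_coils)) {
      phi <- 2 * pi * (cc - 1) / n_coils + stats::rnorm(1, 0, 0.1)
      px <- R * cos(phi); py <- R * sin(phi)
      d2 <- outer((x - px)^2, (y - py)^2, `+`)
      mag <- exp(-d2 / (2 * sigma^2))
      ph0 <- stats::runif(1, 0, 2 * pi)
      gx <- stats::rnorm(1, 0, 0.5) / g[1]
      gy <- stats::rnorm(1, 0, 0.5) / g[2]
      phase <- ph0 + 2 * pi * outer(gx * x, gy * y, `+`)
      plane <- mag * exp(1i * phase)
      zc <- stats::runif(1, min(z), max(z))
      zmod <- 0.85 + 0.15 * cos(2 * pi * (z - zc) / (2 * g[3]))
      for (iz in seq_len(g[3])) maps[, , iz, cc] <- plane * zmod[iz]
    }
  })
  structure(maps, class = "coil_profile")
}

.as_volume_array <- function(volume) {
  if (inherits(volume, "dynamic_volume")) volume$data else volume
}

.as_coil_array <- function(coils) {
  a <- unclass(coils)
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  a
}

## core forward: [nx,ny,nz,nf] image -> [nread, nspokes, nz, nc, nf] samples
.encode_forward <- function(m, coils, pattern, backend) {
  d <- dim(m)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nf <- d[4]
  nc <- dim(coils)[4]
  ns <- pattern$n_readout * pattern$n_spokes_per_frame
  out <- array(0 + 0i, c(pattern$n_readout, pattern$n_spokes_per_frame,
                         nz, nc, nf))
  if (backend == "nufft") plan <- .nufft_plan(pattern, nx, ny)
  else mats <- .dft_plan(pattern, nx, ny)
  K <- nz * nc
  for (f in seq_len(nf)) {
    cm <- array(m[, , , f], c(nx, ny, nz, nc)) * coils   # coil-weighted image
    cm <- .fftz_centered(cm)                             # Cartesian kz
    if (backend == "nufft") {
      cm <- cm / array(plan$deapod, c(nx, ny, nz, nc))
      pad <- array(0 + 0i, c(plan$G, plan$G, K))
      pad[plan$pad_x, plan$pad_y, ] <- array(cm, c(nx, ny, K))
      Fg <- .fft2_many(pad)
      dim(Fg) <- c(plan$G * plan$G, K)
      out[, , , , f] <- .sp_cmult(plan$interp[[f]], Fg)
    } else {
      out[, , , , f] <- mats[[f]] %*% matrix(cm, nx * ny, K)
    }
  }
  out
}

## core adjoint: samples -> image; exact conjugate transpose of the forward
.encode_adjoint <- function(dat, coils, pattern, backend, weights = NULL,
                            per_coil = FALSE) {
  dd <- dim(dat)
  nz <- dd[3]; nc <- dd[4]; nf <- dd[5]
  cd <- dim(coils)
  nx <- cd[1]; ny <- cd[2]
  if (!is.null(weights)) {
    lw <- length(weights)
    if (lw != prod(dd[1:2]) && lw != prod(dd[1:3]))
      stop_invalid("weights must cover [readout, spoke] or [readout, spoke, partition]")
    dat <- dat * array(as.vector(weights), dd)  # recycled over coils, frames
  }
  if (backend == "nufft") plan <- .nufft_plan(pattern, nx, ny)
  else mats <- .dft_plan(pattern, nx, ny)
  K <- nz * nc
  out <- array(0 + 0i, c(nx, ny, nz, if (per_coil) nc else 1L, nf))
  for (f in seq_len(nf)) {
    y <- matrix(dat[, , , , f], ncol = K)
    if (backend == "nufft") {
      gv <- .sp_cmult(plan$interp_t[[f]], y)
      dim(gv) <- c(plan$G, plan$G, K)
      Fg <- .fft2_many(gv, inverse = TRUE)
      img <- array(Fg[plan$pad_x, plan$pad_y, , drop = FALSE],
                   c(nx, ny, nz, nc))
      img <- img / array(plan$deapod, c(nx, ny, nz, nc))
    } else {
      img <- array(Conj(t(mats[[f]])) %*% y, c(nx, ny, nz, nc))
    }
    img <- .fftz_centered(img, inverse = TRUE)   # adjoint of the kz DFT
    if (per_coil) {
      out[, , , , f] <- img * Conj(coils)
    } else {
      comb <- array(0 + 0i, c(nx, ny, nz))
      for (cc in seq_len(nc))
        comb <- comb + array(img[, , , cc, drop = FALSE], c(nx, ny, nz)) *
          array(Conj(coils[, , , cc, drop = FALSE]), c(nx, ny, nz))
      out[, , , 1L, f] <- comb
    }
  }
  if (per_coil) out else array(out, c(nx, ny, nz, nf))
}

#' Forward stack-of-stars encoding
#'
#' Maps a dynamic volume to multicoil stack-of-stars k-space: each frame is
#' multiplied by every coil sensitivity, Fourier-transformed along the
#' Cartesian partition axis (centred kz DFT) and evaluated at the frame's
#' in-plane radial samples (type-2 nonuniform DFT). Optional circular complex
#' Gaussian receiver noise of standard deviation `noise_sd` (per complex
#' sample; each real component has sd `noise_sd / sqrt(2)`) is added in
#' k-space.
#'
#' @param volume a `dynamic_volume` or complex array `[nx, ny, nz, frames]`.
#' @param coils a `coil_profile` (or array `[nx, ny, nz, coils]`).
#' @param pattern a `sampling_pattern` with matching partition and frame
#'   counts.
#' @param noise_sd receiver noise standard deviation (0 = noiseless).
#' @param backend `"nufft"` (Kaiser-Bessel gridding, default) or `"dft"`
#'   (exact direct summation; small grids only).
#' @return object of class `kspace_series`: complex samples
#'   `[readout, spoke, partition, coil, frame]` paired with the pattern.
#' @export
forward <- function(volume, coils, pattern, noise_sd = 0,
                    backend = c("nufft", "dft")) {
  backend <- match.arg(backend)
  stopifnot(inherits(pattern, "sampling_pattern"))
  m <- .as_volume_array(volume)
  ca <- .as_coil_array(coils)
  d <- dim(m)
  if (!all(d[1:3] == dim(ca)[1:3]))
    stop_invalid("volume and coil grids disagree")
  if (d[3] != pattern$n_partitions)
    stop_invalid("volume has %d slices but the pattern encodes %d partitions",
                 d[3], pattern$n_partitions)
  if (d[4] != pattern$n_frames)
    stop_invalid("volume has %d frames but the pattern has %d", d[4],
                 pattern$n_frames)
  dat <- .encode_forward(m, ca, pattern, backend)
  if (noise_sd > 0) {
    n <- length(dat)
    dat <- dat + complex(real = stats::rnorm(n, 0, noise_sd / sqrt(2)),
                         imaginary = stats::rnorm(n, 0, noise_sd / sqrt(2)))
  }
  structure(list(data = dat, pattern = pattern, noise_sd = noise_sd,
                 backend = backend), class = "kspace_series")
}

#' @export
print.kspace_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "k-space series: %d readout x %d spokes x %d partitions x %d coils x %d frames (noise sd %g)\n",
    d[1], d[2], d[3], d[4], d[5], x$noise_sd))
  invisible(x)
}

#' Adjoint stack-of-stars encoding
#'
#' Exact conjugate transpose of [forward()]: type-1 nonuniform DFT in-plane,
#' adjoint Cartesian DFT along kz, conjugate-coil combination. If `weights`
#' are supplied the samples are pre-multiplied (density compensation), giving
#' the regridding operation used by [gridding_recon()].
#'
#' @param data a `kspace_series` (or complex sample array with `pattern`
#'   supplied).
#' @param coils a `coil_profile` matching the reconstruction grid.
#' @param pattern sampling pattern; defaults to the one stored in `data`.
#' @param weights optional per-sample weights `[readout, spoke]` or
#'   `[readout, spoke, partition]`, recycled over coils and frames.
#' @param backend `"nufft"` or `"dft"`; defaults to the backend recorded in
#'   `data`.
#' @return a `dynamic_volume` (provenance `"gridding"`).
#' @export
adjoint <- function(data, coils, pattern = NULL, weights = NULL,
                    backend = NULL) {
  if (inherits(data, "kspace_series")) {
    pattern <- pattern %||% data$pattern
    backend <- backend %||% data$backend
    dat <- data$data
  } else {
    if (is.null(pattern)) stop_invalid("pattern required for raw arrays")
    backend <- backend %||% "nufft"
    dat <- data
  }
  ca <- .as_coil_array(coils)
  dd <- dim(dat)
  if (dd[1] != pattern$n_readout || dd[2] != pattern$n_spokes_per_frame ||
      dd[3] != pattern$n_partitions || dd[5] != pattern$n_frames)
    stop_invalid("k-space dimensions are inconsistent with the pattern")
  if (dd[4] != dim(ca)[4])
    stop_invalid("coil count of data (%d) and maps (%d) disagree",
                 dd[4], dim(ca)[4])
  img <- .encode_adjoint(dat, ca, pattern, backend, weights = weights)
  dynamic_volume(img, voxel_mm = c(1, 1, 1),
                 frame_times = seq_len(dim(img)[4]) - 1, source = "gridding")
}
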