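# Shared fixtures: all inputs are generated in code at test time.

# smooth separable test series (Gaussian blob, slice/frame-scaled)
smooth_series <- function(N = 16L, nz = 2L, nf = 2L) {
  x <- outer(seq(-1, 1, length.out = N)^2, seq(-1, 1, length.out = N)^2, `+`)
  img <- exp(-x / 0.18)
  m <- array(0 + 0i, c(N, N, nz, nf))
  for (f in seq_len(nf)) for (z in seq_len(nz))
    m[, , z, f] <- img * (0.5 + 0.2 * z + 0.1 * f)
  m
}

random_series <- function(N = 16L, nz = 4L, nf = 2L, seed = 1L) {
  with_seed(seed, array(complex(real = rnorm(N * N * nz * nf),
                                imaginary = rnorm(N * N * nz * nf)),
                        c(N, N, nz, nf)))
}

random_samples <- function(pattern, n_coils, seed = 1L) {
  d <- c(pattern$n_readout, pattern$n_spokes_per_frame,
         pattern$n_partitions, n_coils, pattern$n_frames)
  with_seed(seed, array(complex(real = rnorm(prod(d)),
                                imaginary = rnorm(prod(d))), d))
}

# internal helpers shared with test code
with_seed <- starperf:::with_seed
rel_l2 <- starperf:::rel_l2
l2norm <- starperf:::l2norm

# small motion-free, trigger-clean phantom spec
quiet_spec <- function(grid = c(32L, 32L, 4L), n_frames = 8L, seed = 7L,
                       defects = list(), lv = list(endo_mm = 12,
                                                   epi_mm = 22,
                                                   long_axis_mm = 60,
                                                   center_mm = c(0, 0, 0))) {
  phantom_spec(grid = grid, voxel_mm = c(3, 3, 5), lv = lv,
               defects = defects,
               motion = list(amplitude_mm = c(0, 0, 0), period_s = 4),
               trigger = list(rr_s = 1, jitter_sd_s = 0,
                              mistrigger_prob = 0,
                              mistrigger_shift_mm = 0),
               n_frames = n_frames, seed = seed)
}

# independent brute-force stack-of-stars forward operator: plain R loops over
# voxels and samples, written without reference to the package's operators
naive_forward <- function(m, coils, pattern) {
  d <- dim(m)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nf <- d[4]
  nc <- dim(coils)[4]
  kr <- ((seq_len(pattern$n_readout) - 1) - pattern$n_readout / 2) *
    2 * pattern$k_max / pattern$n_readout
  xc <- (seq_len(nx) - 1) - nx / 2
  yc <- (seq_len(ny) - 1) - ny / 2
  zc <- (seq_len(nz) - 1) - nz / 2
  kzv <- ((seq_len(nz) - 1) - nz / 2) / nz
  out <- array(0 + 0i, c(pattern$n_readout, pattern$n_spokes_per_frame,
                         nz, nc, nf))
  for (f in seq_len(nf)) for (cc in seq_len(nc)) {
    w <- m[, , , f] * coils[, , , cc]
    for (sp in seq_len(pattern$n_spokes_per_frame)) {
      th <- pattern$angle_schedule[f, sp]
      for (ir in seq_len(pattern$n_readout)) {
        kx <- kr[ir] * cos(th); ky <- kr[ir] * sin(th)
        for (ip in seq_len(nz)) {
          ph <- exp(-2i * pi * (outer(kx * xc, ky * yc, `+`)))
          acc <- 0 + 0i
          for (iz in seq_len(nz))
            acc <- acc + sum(w[, , iz] * ph) * exp(-2i * pi * kzv[ip] * zc[iz])
          out[ir, sp, ip, cc, f] <- acc
        }
      }
    }
  }
  out
}

temp_path <- function(ext) tempfile(fileext = ext)
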