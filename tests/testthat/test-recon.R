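test_that("gridding reconstruction is linear and maps zero to zero", {
  pat <- build_pattern(n_readout = 16L, n_spokes_per_frame = 4L,
                       n_frames = 2L, n_partitions = 2L)
  co <- simulate_coils(c(8L, 8L, 2L), 2L, seed = 1L)
  d1 <- forward(random_series(8L, 2L, 2L, seed = 1L), co, pat,
                backend = "dft")
  d2 <- forward(random_series(8L, 2L, 2L, seed = 2L), co, pat,
                backend = "dft")
  z <- d1; z$data <- array(0 + 0i, dim(d1$data))
  expect_true(all(gridding_recon(z, co)$data == 0))
  mix <- d1; mix$data <- 2 * d1$data + 3i * d2$data
  g1 <- gridding_recon(d1, co)$data
  g2 <- gridding_recon(d2, co)$data
  gm <- gridding_recon(mix, co)$data
  expect_lt(rel_l2(gm, 2 * g1 + 3i * g2), 1e-9)
})

test_that("fully sampled gridding recovers a smooth phantom within 5% NRMSE", {
  N <- 32L
  m <- smooth_series(N, 4L, 2L)
  nsp <- as.integer(ceiling(pi / 2 * N))
  pat <- build_pattern(n_readout = 2L * N, n_spokes_per_frame = nsp,
                       n_frames = 2L, n_partitions = 4L)
  co <- simulate_coils(c(N, N, 4L), 4L, seed = 3L)
  ks <- forward(m, co, pat)
  gr <- gridding_recon(ks, co)
  expect_lt(rel_l2(gr$data, m), 0.05)
  # rss combine also recovers the magnitude (slightly more biased than the
  # sensitivity-weighted combine near the coil-map floor)
  grr <- gridding_recon(ks, co, combine = "rss")
  expect_lt(rel_l2(Mod(grr$data), Mod(m)), 0.08)
})

test_that("fidelity-only cost equals the squared residual and vanishes at truth", {
  pat <- build_pattern(n_readout = 16L, n_spokes_per_frame = 8L,
                       n_frames = 2L, n_partitions = 2L)
  co <- simulate_coils(c(8L, 8L, 2L), 2L, seed = 1L)
  m <- smooth_series(8L, 2L, 2L)
  dat <- forward(m, co, pat, backend = "dft")
  cfg0 <- recon_config(alpha_t = 0, alpha_s = 0, epsilon = 1e-3,
                       backend = "dft")
  at_truth <- stcr_cost(m, dat, co, config = cfg0)
  expect_lt(at_truth$cost, 1e-18 * sum(Mod(dat$data)^2))
  m2 <- m + 0.1
  c2 <- stcr_cost(m2, dat, co, config = cfg0)
  r <- forward(m2, co, pat, backend = "dft")$data - dat$data
  expect_equal(c2$cost, sum(Mod(r)^2), tolerance = 1e-12)
  expect_equal(unname(c2$terms["fidelity"]), c2$cost, tolerance = 1e-12)
})

test_that("analytic STCR gradient matches central finite differences", {
  pat <- build_pattern(n_readout = 16L, n_spokes_per_frame = 3L,
                       n_frames = 3L, n_partitions = 2L)
  co <- simulate_coils(c(8L, 8L, 2L), 2L, seed = 2L)
  m0 <- random_series(8L, 2L, 3L, seed = 10L)
  dat <- forward(m0, co, pat, backend = "dft")
  m <- m0 + 0.3 * random_series(8L, 2L, 3L, seed = 11L)
  cfg <- recon_config(alpha_t = 0.5, alpha_s = 0.1, epsilon = 1e-3,
                      backend = "dft")
  err <- starperf:::.gradient_fd_error(m, dat, co, pat, cfg)
  expect_lt(err, 1e-6)
})

test_that("STCR with zero weights converges to truth on fully sampled data", {
  N <- 16L
  m <- smooth_series(N, 2L, 2L)
  nsp <- as.integer(ceiling(pi / 2 * N))
  pat <- build_pattern(n_readout = 2L * N, n_spokes_per_frame = nsp,
                       n_frames = 2L, n_partitions = 2L)
  co <- simulate_coils(c(N, N, 2L), 2L, seed = 3L)
  ks <- forward(m, co, pat)
  cfg <- recon_config(alpha_t = 0, alpha_s = 0, max_iter = 50L, tol = 0)
  rec <- stcr_reconstruct(ks, co, config = cfg)
  expect_lt(rel_l2(rec$volume$data, m), 0.05)
  expect_true(all(diff(rec$cost_trace) <= 1e-12 * rec$cost_trace[1]))
  expect_identical(rec$volume$source, "stcr")
})

test_that("termination gradient norm shrinks as the iteration budget grows", {
  pat <- build_pattern(n_readout = 16L, n_spokes_per_frame = 4L,
                       n_frames = 2L, n_partitions = 2L)
  co <- simulate_coils(c(8L, 8L, 2L), 2L, seed = 1L)
  m <- smooth_series(8L, 2L, 2L)
  ks <- forward(m, co, pat, backend = "dft")
  gn <- vapply(c(5L, 25L, 100L), function(it) {
    cfg <- recon_config(alpha_t = 0, alpha_s = 0, max_iter = it, tol = 0,
                        backend = "dft")
    rec <- stcr_reconstruct(ks, co, config = cfg)
    l2norm(stcr_cost(rec$volume, ks, co, config = cfg)$gradient)
  }, numeric(1))
  expect_true(all(diff(gn) < 0))
})

test_that("temporal TV suppresses frame-to-frame undersampling flicker", {
  # static object sampled with rotating golden-angle spokes at ~8x
  # undersampling: gridding flickers, temporally constrained recon must not
  spec <- quiet_spec(grid = c(32L, 32L, 2L), n_frames = 10L)
  ph <- render_dynamic_phantom(spec)
  stat <- ph$volume$data
  for (f in seq_len(10)) stat[, , , f] <- stat[, , , 5]   # freeze kinetics
  pat <- build_pattern(n_readout = 64L, n_spokes_per_frame = 7L,
                       n_frames = 10L, n_partitions = 2L)
  co <- simulate_coils(c(32L, 32L, 2L), 4L, seed = 4L)
  ks <- with_seed(6, forward(stat, co, pat, noise_sd = 0.1))
  myo <- ph$truth$labels[, , , 5] == 2L
  series_sd <- function(vol) {
    mm <- apply(vol, 4, function(v) mean(Mod(v)[myo]))
    sd(mm)
  }
  gr <- gridding_recon(ks, co)
  cfg <- recon_config(alpha_t = 30, alpha_s = 6, max_iter = 25L,
                      tol = 1e-6)
  rec <- stcr_reconstruct(ks, co, config = cfg)
  expect_lt(series_sd(rec$volume$data), series_sd(gr$data))
})

test_that("denoised time series stay inside the data range plus noise", {
  # fully sampled, temporal-TV-only denoising: no new temporal extrema
  N <- 8L
  m <- smooth_series(N, 1L, 6L)
  nsp <- as.integer(ceiling(pi / 2 * N))
  pat <- build_pattern(n_readout = 2L * N, n_spokes_per_frame = nsp,
                       n_frames = 6L, n_partitions = 1L)
  co <- simulate_coils(c(N, N, 1L), 1L)
  noise_sd <- 0.05
  ks <- with_seed(9, forward(m, co, pat, noise_sd = noise_sd))
  gr <- gridding_recon(ks, co)$data
  cfg <- recon_config(alpha_t = 5, alpha_s = 0, max_iter = 30L, tol = 1e-7)
  rec <- stcr_reconstruct(ks, co, config = cfg)$volume$data
  for (i in seq_len(N * N)) {
    ts_dat <- Mod(gr[(i - 1) %% N + 1, (i - 1) %/% N + 1, 1, ])
    ts_rec <- Mod(rec[(i - 1) %% N + 1, (i - 1) %/% N + 1, 1, ])
    expect_true(all(ts_rec <= max(ts_dat) + noise_sd + 1e-6))
    expect_true(all(ts_rec >= min(ts_dat) - noise_sd - 1e-6))
  }
})

test_that("diverging fixed-step iterations raise a diverged condition with trace", {
  pat <- build_pattern(n_readout = 16L, n_spokes_per_frame = 4L,
                       n_frames = 2L, n_partitions = 2L)
  co <- simulate_coils(c(8L, 8L, 2L), 2L, seed = 1L)
  ks <- forward(smooth_series(8L, 2L, 2L), co, pat, backend = "dft")
  cfg <- recon_config(alpha_t = 0, alpha_s = 0, max_iter = 60L,
                      step = "fixed", step_size = 10, backend = "dft")
  cond <- tryCatch(stcr_reconstruct(ks, co, config = cfg),
                   starperf_diverged = function(e) e)
  expect_s3_class(cond, "starperf_diverged")
  expect_true(length(cond$trace) >= 1)
})

test_that("L-curve: degenerate grids, monotone trade-off, curvature corner", {
  expect_error(lcurve_select(structure(list(), class = "kspace_series"),
                             NULL, NULL, alpha_grid = numeric()),
               class = "starperf_invalid_argument")
  spec <- quiet_spec(grid = c(16L, 16L, 2L), n_frames = 6L)
  ph <- render_dynamic_phantom(spec)
  pat <- build_pattern(n_readout = 32L, n_spokes_per_frame = 4L,
                       n_frames = 6L, n_partitions = 2L)
  co <- simulate_coils(c(16L, 16L, 2L), 2L, seed = 5L)
  ks <- with_seed(8, forward(ph$volume, co, pat, noise_sd = 0.2))
  # converged solves: the monotone trade-off holds only at the solutions
  cfg <- recon_config(max_iter = 60L, tol = 1e-8)

  one <- lcurve_select(ks, co, alpha_grid = 5, config = cfg)
  expect_equal(one$alpha_t, 5)
  expect_equal(one$corner_index, 1L)

  grid <- c(0.5, 2, 8, 32, 128)
  sel <- lcurve_select(ks, co, alpha_grid = grid, config = cfg)
  expect_true(all(diff(sel$table$residual) >= -1e-6 * sel$table$residual[-1]))
  expect_true(all(diff(sel$table$penalty) <= 1e-6 * sel$table$penalty[-1]))

  # independent curvature oracle: fit the circumcentre of each point triple
  # by solving the perpendicular-bisector equations, curvature = 1/radius
  circum_curvature <- function(x, y) {
    vapply(2:(length(x) - 1), function(i) {
      A <- 2 * matrix(c(x[i - 1] - x[i], y[i - 1] - y[i],
                        x[i + 1] - x[i], y[i + 1] - y[i]),
                      2, 2, byrow = TRUE)
      b <- c(x[i - 1]^2 - x[i]^2 + y[i - 1]^2 - y[i]^2,
             x[i + 1]^2 - x[i]^2 + y[i + 1]^2 - y[i]^2)
      ctr <- tryCatch(solve(A, b), error = function(e) c(Inf, Inf))
      r <- sqrt((x[i] - ctr[1])^2 + (y[i] - ctr[2])^2)
      if (is.finite(r) && r > 0) 1 / r else 0
    }, numeric(1))
  }
  kap <- circum_curvature(log(sel$table$residual), log(sel$table$penalty))
  expect_equal(sel$corner_index, which.max(kap) + 1L)
  expect_error(lcurve_select(ks, co, alpha_grid = c(1, NA), config = cfg),
               class = "starperf_invalid_argument")
})
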