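test_that("gamma-variate input is causal with peak A at t0 + alpha*beta", {
  t <- seq(0, 40, by = 0.01)
  c1 <- aif_curve(t, A = 3, t0 = 5, alpha = 2.5, beta = 1.5)
  expect_true(all(c1[t <= 5] == 0))
  expect_equal(max(c1), 3, tolerance = 1e-6)
  expect_equal(t[which.max(c1)], 5 + 2.5 * 1.5, tolerance = 0.011)
  # frozen closed-form value at t0 + 2*alpha*beta for A=1, alpha=2, beta=3,
  # confirmed against dense-grid evaluation
  expect_equal(aif_curve(10 + 12, A = 1, t0 = 10, alpha = 2, beta = 3),
               0.541341132946, tolerance = 1e-9)
  expect_error(aif_curve(t, alpha = -1), class = "starperf_invalid_argument")
})

test_that("tissue concentration matches impulse response and integrator limits", {
  dt <- 0.01
  n <- 2000L
  imp <- c(1 / dt, rep(0, n - 1))   # unit-area discrete impulse
  C <- tissue_concentration(imp, Ktrans = 0.05, kep = 0.3, dt = dt)
  tt <- (seq_len(n) - 1) * dt
  # trapezoidal halves the impulse mass at t = 0
  expect_equal(C[-1] / (0.05 * exp(-0.3 * tt[-1])), rep(0.5, n - 1),
               tolerance = 1e-3)
  aif <- aif_curve(tt, A = 4, t0 = 2, alpha = 2.5, beta = 1.5)
  C0 <- tissue_concentration(aif, Ktrans = 0.04, kep = 0, dt = dt)
  expect_equal(C0[n], 0.04 * sum((aif[-1] + aif[-n]) / 2 * dt),
               tolerance = 1e-10)
})

test_that("coarse-step tissue curves agree with a fine-step reference at the peak", {
  f <- function(dt) {
    tt <- seq(0, 30, by = dt)
    aif <- aif_curve(tt, A = 4, t0 = 2, alpha = 2.5, beta = 1.5)
    max(tissue_concentration(aif, Ktrans = 0.04, kep = 0.2, dt = dt))
  }
  expect_equal(f(0.1), f(0.001), tolerance = 0.01)
})

test_that("saturation-recovery signal has the right baseline, ceiling and monotonicity", {
  expect_equal(signal_from_concentration(0, 2, 0.8, 4.5, 0.1),
               2 * (1 - exp(-0.08)))
  expect_equal(signal_from_concentration(1e9, 2, 0.8, 4.5, 0.1), 2,
               tolerance = 1e-9)
  C <- with_seed(3, sort(runif(50, 0, 8)))
  S <- signal_from_concentration(C, 1.5, 0.85, 4.5, 0.1)
  expect_true(all(diff(S) > 0))
  expect_error(signal_from_concentration(1, 1, 1, 1, TS = 0),
               class = "starperf_invalid_argument")
})

test_that("trigger simulation is degenerate-exact, deterministic and binomially calibrated", {
  s0 <- quiet_spec(n_frames = 16L)
  tr <- simulate_triggers(s0)
  expect_equal(tr$offset_s, rep(0, 16))
  expect_false(any(tr$mistriggered))

  s1 <- phantom_spec(n_frames = 10000L, seed = 42L,
                     trigger = list(rr_s = 1, jitter_sd_s = 0.01,
                                    mistrigger_prob = 0.1,
                                    mistrigger_shift_mm = 6))
  a <- simulate_triggers(s1)
  b <- simulate_triggers(s1)
  expect_identical(a, b)
  frac <- mean(a$mistriggered)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("static spec renders static anatomy with evolving intensity", {
  spec <- quiet_spec(n_frames = 6L)
  ph <- render_dynamic_phantom(spec)
  lab <- ph$truth$labels
  for (f in 2:6) expect_identical(lab[, , , f], lab[, , , 1])
  # bloodpool intensity evolves with the bolus
  bp <- apply(ph$volume$data, 4, function(v) mean(Mod(v[lab[, , , 1] == 1L])))
  expect_gt(max(bp) / bp[1], 3)
})

test_that("ground-truth labels partition the grid and bloodpool peaks first", {
  spec <- quiet_spec(n_frames = 20L,
                     defects = list(list(angle_deg = c(240, 300),
                                         partitions = c(1, 3),
                                         transmural = 1,
                                         flow_reduction = 0.5)))
  ph <- render_dynamic_phantom(spec)
  expect_true(all(ph$truth$labels %in% 0:3))
  expect_equal(prod(dim(ph$truth$labels)),
               prod(spec$grid) * spec$n_frames)
  cv <- ph$truth$curves
  expect_lt(which.max(cv$aif), which.max(cv$myocardium))
})

test_that("defect intensity at myocardial peak falls below remote myocardium", {
  spec <- quiet_spec(n_frames = 20L,
                     defects = list(list(angle_deg = c(240, 300),
                                         partitions = c(1, 3),
                                         transmural = 1,
                                         flow_reduction = 0.5)))
  ph <- render_dynamic_phantom(spec)
  f <- which.max(ph$truth$curves$myocardium)
  lab <- ph$truth$labels[, , , f]
  v <- Mod(ph$volume$data[, , , f])
  expect_lt(mean(v[lab == 3L]), mean(v[lab == 2L]))
})

test_that("defect depth grows monotonically with flow reduction", {
  depth_of <- function(fr) {
    spec <- quiet_spec(n_frames = 20L,
                       defects = list(list(angle_deg = c(240, 300),
                                           partitions = c(1, 3),
                                           transmural = 1,
                                           flow_reduction = fr)))
    ph <- render_dynamic_phantom(spec)
    f <- which.max(ph$truth$curves$myocardium)
    lab <- ph$truth$labels[, , , f]
    v <- Mod(ph$volume$data[, , , f])
    1 - mean(v[lab == 3L]) / mean(v[lab == 2L])
  }
  d <- vapply(c(0.2, 0.5, 0.8), depth_of, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("sub-voxel analytic translation only moves boundary voxels", {
  spec <- phantom_spec(grid = c(32L, 32L, 4L), voxel_mm = c(3, 3, 5),
                       lv = list(endo_mm = 12, epi_mm = 22,
                                 long_axis_mm = 60, center_mm = c(0, 0, 0)),
                       motion = list(amplitude_mm = c(1.2, 1.2, 0),
                                     period_s = 4),
                       trigger = list(rr_s = 1, jitter_sd_s = 0,
                                      mistrigger_prob = 0,
                                      mistrigger_shift_mm = 0),
                       n_frames = 6L, seed = 2L)
  ph <- render_dynamic_phantom(spec)
  counts <- apply(ph$truth$labels, 4, function(l) tabulate(l + 1L, 4L))
  # re-rasterising the analytically shifted shapes can only flip voxels in a
  # thin boundary shell: relative count drift is bounded by
  # perimeter * |shift| / area of each region's cross-section
  shift_vox <- sqrt(2) * 1.2 / 3                 # diagonal shift in voxels
  endo_v <- 12 / 3; epi_v <- 22 / 3
  bound_blood <- 2 * shift_vox / endo_v
  bound_myo <- 2 * shift_vox * (endo_v + epi_v) / (epi_v^2 - endo_v^2)
  total <- prod(dim(ph$truth$labels)[1:3])
  for (f in 2:6) {
    expect_lt(abs(sum(ph$truth$labels[, , , f] == 1L) -
                    sum(ph$truth$labels[, , , 1] == 1L)) /
                sum(ph$truth$labels[, , , 1] == 1L), bound_blood)
    expect_lt(abs(sum(ph$truth$labels[, , , f] == 2L) -
                    sum(ph$truth$labels[, , , 1] == 2L)) /
                sum(ph$truth$labels[, , , 1] == 2L), bound_myo)
  }
  # background absorbs the complement: its relative drift is tiny
  expect_lt(diff(range(counts[1, ])) / mean(counts[1, ]), 0.02)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(lv = list(endo_mm = 30, epi_mm = 20,
                                      long_axis_mm = 80,
                                      center_mm = c(0, 0, 0))),
               class = "starperf_invalid_argument")
  expect_error(quiet_spec(defects = list(list(angle_deg = c(0, 90),
                                              partitions = c(1, 99),
                                              transmural = 1,
                                              flow_reduction = 0.5))),
               class = "starperf_invalid_argument")
  expect_error(quiet_spec(defects = list(list(angle_deg = c(0, 90),
                                              partitions = c(1, 2),
                                              transmural = 0,
                                              flow_reduction = 0.5))),
               class = "starperf_invalid_argument")
})
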