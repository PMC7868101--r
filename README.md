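# starperf

Desk-scale simulation, reconstruction and reading of **free-breathing 3D
stack-of-stars first-pass myocardial perfusion MRI**.

Stress perfusion CMR images the first pass of a gadolinium bolus through
the myocardium, one T1-weighted volume per cardiac cycle; hypoperfused
territory enhances more slowly than remote myocardium. Whole-heart coverage
within a ~190 ms shot during free breathing requires a motion-tolerant,
heavily undersampled acquisition — radial golden-angle spokes in-plane with
Cartesian partition encoding along the left-ventricular long axis (the
stack-of-stars) — and an iterative reconstruction that regularises across
time. A practical complication is that undersampled first-pass series show
*transient* dark myocardial patches during bolus arrival that mimic
perfusion defects; genuine defects are distinguished by their temporal
persistence, depth and transmurality.

`starperf` packages that entire loop for simulation studies:

* **phantom** — analytic dynamic LV phantom: gamma-variate arterial input
  `c(t) = A ((t−t0)/αβ)^α e^{α−(t−t0)/β}`, one-compartment myocardium
  `C(t) = Ktrans ∫ c(τ) e^{−kep(t−τ)} dτ`, saturation-recovery signal
  `S = M0 (1 − e^{−TS(R1,0 + r1 C)})`, wedge-shaped defects of graded flow
  reduction and transmurality, sinusoidal respiratory translation, ECG
  jitter and mis-triggering.
* **sampling/encoding** — golden-angle (111.246°) stack-of-stars patterns,
  ramp density compensation, multicoil forward/adjoint operators with two
  interchangeable backends (exact direct DFT as oracle; Kaiser–Bessel
  gridding for speed), exact adjointness by construction.
* **recon** — non-iterative density-compensated gridding (the trial-run
  image) and **STCR**, minimising
  `‖Em − d‖² + α_t Σ√(|Δ_t m|² + ε²) + α_s Σ√(|Δ_x m|² + |Δ_y m|² + ε²)`
  by backtracking gradient descent, plus L-curve (maximum-curvature)
  selection of `α_t`.
* **analysis** — slab-edge display policy (16 partitions → 12 displayed
  5 mm slices), AHA 16-segment signal-time curves, transient-artifact vs
  persistent-defect classification, composite severity grading
  (depth × transmurality × persistence), and segment-level recovery
  metrics against ground truth.

## Worked example

Simulate a stress acquisition with one severe inferior defect, reconstruct
with STCR, and read the segments:

```r
library(starperf)

spec <- phantom_spec(
  grid = c(64L, 64L, 8L), voxel_mm = c(3, 3, 5),
  lv = list(endo_mm = 17, epi_mm = 30, long_axis_mm = 80,
            center_mm = c(0, 0, 20)),
  defects = list(list(angle_deg = c(240, 300), partitions = c(1, 6),
                      transmural = 1, flow_reduction = 0.8)),
  motion = list(amplitude_mm = c(0.5, 1, 1), period_s = 4),
  trigger = list(rr_s = 1, jitter_sd_s = 0.005, mistrigger_prob = 0,
                 mistrigger_shift_mm = 0),
  n_frames = 24L, seed = 31L)
ph   <- render_dynamic_phantom(spec)
pat  <- build_pattern(n_readout = 128L, n_spokes_per_frame = 13L,
                      n_frames = 24L, n_partitions = 8L)   # ~8x undersampled
coils <- simulate_coils(spec$grid, 4L, seed = 32L)
raw  <- forward(ph$volume, coils, pat, noise_sd = 0.4)

rec  <- stcr_reconstruct(raw, coils, config = recon_config(max_iter = 20L))
vol  <- discard_edge_slices(
  dynamic_volume(rec$volume$data, spec$voxel_mm, ph$volume$frame_times,
                 "stcr"), 2L)
model    <- lv_model(spec, ph$truth, n_edge = 2L)
curves   <- aha_segment_curves(vol, model)
findings <- classify_hypointensity(curves)
subset(as.data.frame(findings), classification == "persistent-defect")
```

```
        segment segment_id onset persistence     depth transmurality
 basal-inferior          4     7          18 0.4577131             1
   mid-inferior         10     7          18 0.4587409             1
    classification severity     score
 persistent-defect moderate 0.3432849
 persistent-defect moderate 0.3440557
```

The inferior wedge is flagged as a persistent, transmural, moderate-graded
defect in the basal and mid inferior segments: a ~46% intensity deficit
versus remote myocardium lasting 18 of 24 cardiac cycles, starting at bolus
arrival and outlasting the bolus window. Transient bolus-arrival dips in
other segments (when present) are classified as artifacts, and on the
matched defect-free control series the classifier reports no persistent
finding.

A command-line wrapper over the same functions is installed at
`inst/cli/starperf.R`:

```sh
Rscript inst/cli/starperf.R simulate --out run1 --seed 7
Rscript inst/cli/starperf.R recon --in run1/raw.h5 --out run1/stcr.nii.gz --method stcr
Rscript inst/cli/starperf.R analyze --in run1/stcr.nii.gz --truth run1/gt.h5 \
        --config run1/config.yaml --out run1
Rscript inst/cli/starperf.R selftest
```

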