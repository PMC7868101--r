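---
title: "Simulating and reconstructing free-breathing 3D stack-of-stars first-pass myocardial perfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reconstructing free-breathing 3D stack-of-stars first-pass myocardial perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stress first-pass perfusion (FPP) CMR images the transit of a gadolinium
bolus through the myocardium, one T1-weighted volume (or slice set) per
cardiac cycle; regions that enhance more slowly than remote myocardium mark
impaired perfusion. Conventional 2D FPP covers only about three slices per
cycle. Whole-heart coverage ("3D FPP") within a ~190 ms shot demands heavy
undersampling, and doing it during free breathing additionally demands
tolerance to respiratory motion — which motivates the stack-of-stars (SOS)
acquisition: golden-angle radial spokes in-plane (robust to motion and
angular undersampling, repeatedly refreshing the k-space centre) combined
with Cartesian partition encoding along the left-ventricular long axis,
where coarser resolution suffices.

`starperf` provides a desk-scale laboratory for this acquisition class: a
dynamic contrast-enhanced cardiac phantom, multicoil SOS encoding operators,
the two reconstructions used in practice — instant density-compensated
gridding for trial runs and iterative spatio-temporal constrained
reconstruction (STCR) for diagnostic reading — and an automatic reader that
converts reconstructed series into AHA 16-segment curves and discriminates
transient dark artefacts from persistent perfusion defects.

## Sampling model

A `sampling_pattern` holds the full acquisition geometry. In-plane spokes
advance by the golden angle, $\pi(\sqrt5-1)/2 \approx 111.246^\circ$,
continuously across the whole series by default, so any consecutive subset
of spokes covers $[0,\pi)$ near-uniformly (the three-distance property of
irrational rotations bounds the angular gaps; the test suite asserts it by
enumeration). Spokes are *not* rotated between kz partitions: an aligned
stack keeps the partition axis a separable Cartesian FFT. Partition
ordering is centric by default — the k-space centre is acquired first, so
the contrast-defining data coincide with the end-systolic pause the shot is
timed to.

Radial sample coordinates are normalised to cycles per voxel spacing with
$k_{\max}=0.5$ (Nyquist); readout oversampling of 2 doubles the samples per
spoke at half the radial spacing. The DC voxel of every centred transform
sits at 0-based index $N/2$, and even grid extents are required throughout.

Shot-duration accounting multiplies the repetition time by the lines per
shot (spokes per frame × encoded partitions). The default stack — 10 spokes
× 16 partitions at TR 1.175 ms — gives the 188 ms shot the sequence design
targets. These timing defaults are package decisions chosen to reproduce
that product with a realistic ultrafast-gradient-echo TR; they are not a
claim about any particular scanner protocol.

Density compensation is the analytic ramp $w \propto |k|$. The DC sample of
each spoke takes the continuum limit of the ramp integrated over its
half-cell, $\Delta k/8$ (this tie-break is what makes the weights strictly
positive). Weights are normalised so one frame's total equals the sampled
disc area times the partition count, which makes the weighted adjoint an
approximate inverse with no further scale factor.

## Phantom

The phantom is analytic: an ellipsoidal-shell left ventricle (full radius
over the basal half of the long axis, ellipsoidal taper to the apex)
rasterised on the voxel grid, inside a static torso ellipse. Contrast
kinetics use standard tracer-kinetic building blocks:

* arterial input: peak-normalised gamma-variate
  $c(t) = A\,((t-t_0)/\alpha\beta)^{\alpha} e^{\alpha-(t-t_0)/\beta}$,
  defaults $A=4$ mM, $t_0=4$ s, $\alpha=2.5$, $\beta=1.5$ s — a first-pass
  bolus peaking ~4 s after arrival at a blood concentration typical of a
  0.1 mmol/kg injection;
* myocardium: one-compartment model
  $C(t)=K^{trans}\int_0^t c(\tau)e^{-k_{ep}(t-\tau)}d\tau$ (trapezoidal
  convolution, evaluated recursively in $O(n)$), defaults
  $K^{trans}=0.035\,/s$, $k_{ep}=0.15\,/s$ — stress-level flow;
* signal: saturation recovery $S = M_0(1-e^{-T_S(R_{1,0}+r_1 C)})$ with
  $T_S=100$ ms, $r_1 = 4.5\,/(\mathrm{mM\,s})$ (gadobutrol at 3 T),
  $R_{1,0}$ of blood/myocardium from their native T1.

No quantitative kinetic parameters are claimed to reproduce patient data;
the defaults are chosen once so that the qualitative first-pass orderings
hold (blood pool peaks before myocardium; enhancement is strongly
T1-weighted; defect deficit grows monotonically with flow reduction), and
the tests assert exactly those orderings.

Defects are wedges specified by angular span, partition span, transmural
fraction (measured from the endocardium) and flow reduction; they scale
$K^{trans}$ by $1-\text{flow reduction}$. Respiratory motion is a rigid
sinusoidal translation, one position per cardiac cycle, with the dominant
component along the slab axis; geometry is re-rendered analytically at each
frame position rather than interpolated, so reconstruction tests are never
confounded by resampling blur. The cost of that choice is that rasterised
region voxel counts may drift by a thin boundary shell between frames
(bounded by perimeter × shift; asserted in the tests), since exact count
conservation under sub-voxel shifts of a fixed lattice is impossible.

ECG triggering draws per-frame offsets from Normal(0, jitter sd); with the
configured mis-trigger probability a frame instead draws a uniform offset
up to half the RR interval and receives an extra geometry jolt — the
wrong-cardiac-phase appearance of mis-triggered frames. All randomness
flows from the spec seed through fixed component offsets, so every output
is reproducible bit for bit.

Transient dark artefacts are deliberately *not* injected: they emerge from
angular undersampling interacting with the sharp bloodpool-to-myocardium
contrast at bolus arrival, which is the mechanism the analysis module is
meant to discriminate from true defects.

## Encoding

Two interchangeable backends implement the multicoil SOS operator
$E = \mathcal{S}\,\mathcal{F}_{xy}\,\mathcal{F}_z\,C$: coil multiplication,
centred Cartesian DFT along kz, in-plane nonuniform Fourier sampling.

* `dft`: exact direct summation; the oracle, restricted to small in-plane
  grids (≤ 2048 pixels).
* `nufft`: Kaiser–Bessel gridding on a 2× oversampled grid. The kernel
  width is 8 cells (Beatty β), chosen so the backend matches the exact DFT
  to ~1e-7 relative — comfortably inside the 1e-5 equivalence contract; a
  width of 4 was measured at ~1e-3 and rejected. Deapodisation uses the
  kernel's transform computed by Simpson quadrature; the fftshift
  permutations are folded into the sparse interpolation indices, and the
  per-frame sparse matrices are cached on the pattern.

The adjoint is the exact conjugate transpose of the forward operator in
both backends (the dot-product identity holds to ~1e-16 in the DFT backend),
which is what the gradient of the STCR data-fidelity term requires. Receiver
noise is circular complex Gaussian added in k-space. Coil maps are smooth
Gaussian-bump sensitivities treated as known; no self-calibration.

## Reconstruction

Gridding: density-compensated adjoint with sensitivity-weighted coil
combination (RSS optional), normalised so a fully sampled unit-magnitude
object reconstructs near unit magnitude. It is the near-instantaneous
trial-run image: low quality under undersampling but immediate.

STCR minimises
$$J(m) = \|Em-d\|_2^2
 + \alpha_t \sum \sqrt{|\Delta_t m|^2+\epsilon^2}
 + \alpha_s \sum \sqrt{|\Delta_x m|^2+|\Delta_y m|^2+\epsilon^2}$$
with forward differences, no temporal wraparound, isotropic in-plane
spatial TV and no kz smoothing (the through-plane resolution is already the
coarsest dimension; a kz penalty would blur the slice direction the display
policy protects). Gradients are smoothed-TV derivatives; the analytic
gradient matches central finite differences to ~1e-10 on small instances.
$\epsilon$ defaults to $10^{-8}\times$ the median k-space magnitude, making
the penalty scale-invariant in the measured data.

The optimiser is plain gradient descent with Armijo backtracking
($c=10^{-4}$, shrink 0.5, step doubling after acceptance) — the simplest
scheme whose accepted-step cost trace is provably nonincreasing. The
forward projection of the descent direction is cached, so line-search
trials cost only array arithmetic. Initialisation is the gridding image.
Termination: `max_iter` or relative cost change below `tol`; a non-finite
cost raises a `starperf_diverged` condition carrying the trace.

Weighting parameters follow the method's practice: they were optimised once
during package set-up and are not adjusted per case. The set-up calibration
ran `lcurve_select()` — maximum Menger curvature of the (log residual,
log penalty) polyline — on the default simulated configuration (64×64×16,
32 frames, 10 spokes/frame, 8 coils, seeded receiver noise) over the
candidate grid {10, 30, 100, 300, 1000}; the corner fell at
`alpha_t = 100`, which is the package default, with
`alpha_s = 0.2 * alpha_t = 20`. The spatial weight is kept subordinate
because the temporal constraint carries most of the burden for dynamic
radial data. `lcurve_select()` is the supported way
to re-derive weights for a different configuration.

## Analysis

The display policy discards half the configured edge slices from each slab
end (default 4 of 16, leaving 12 displayed slices), as slab-selective 3D
imaging always does. Myocardial voxels are assigned to the 16 AHA segments
by long-axis band (basal/mid/apical thirds of the LV-bearing slices) and
circumferential sector around the per-frame LV centre; in simulation mode
the geometry comes from the phantom spec and ground-truth shifts, so
segmentation error never contaminates reconstruction scoring.

Classification works on per-segment mean-magnitude curves. The remote
reference is the mean of segments that never dip below threshold (median
segment if all dip — a logged global-artifact fallback). A segment is
hypointense at frame $t$ if its curve falls below
$(1-\text{threshold})\times$ remote, threshold 0.15. Runs of hypointense
frames lasting at least `persist_min` = 5 frames *and* extending beyond ±3
frames around the blood-pool peak are persistent defects; everything else —
in particular the 2–3-frame dips that ride on peak blood-myocardium
contrast, the dark-rim-type transients — is a transient artifact. The
window and persistence defaults deliberately place 2–3-frame bolus-arrival
dips on the artifact side by construction.

Transmurality is estimated by splitting each segment into endocardial and
epicardial halves and scoring each half's deficit against the threshold.
Severity is the composite
$s = \text{depth} \times \text{transmurality} \times
\min(1, \text{persistence}/\text{pass length})$, graded severe ≥ 0.5,
moderate ≥ 0.2, mild ≥ 0.05. These boundaries are declared package
conventions — clinical grading is a reader impression, and agreement with
any particular clinical grading is qualitative, not a validation claim.
Recovery against ground truth is scored at segment granularity
(sensitivity by severity, specificity, Dice), with true segments defined by
≥ 25% myocardial-voxel overlap with a defect wedge.

## What the simulations do and do not show

The generator emulates first-pass enhancement, graded regional
hypoperfusion, rigid respiratory motion, ECG mis-triggering, coil
sensitivity structure and receiver noise. It does not emulate realistic
torso anatomy, off-resonance or B0 effects, intra-shot (within-cycle)
motion, through-plane cardiac contraction, or the full physics of dark-rim
artefacts beyond what undersampling itself induces. Passing tests therefore
demonstrate the internal consistency and the designed discrimination
behaviour of the pipeline on data whose ground truth is known — they do not
demonstrate diagnostic performance on patients.

Problem sizes in the tests and the acceptance script are desk-scale by
design: operator checks on 16×16×4 grids, convergence on 16×16×2, the
defect-recovery surface on a 64×64×8 slab over 24 cardiac cycles at ~8×
angular undersampling with 4 coils. These sizes were chosen so the full
suite runs in minutes on one core while keeping every qualitative regime of
the method (undersampling flicker, bolus transients, persistent deficits)
present in the data.

## Known limitations

* Gradient descent is deliberately simple; conjugate-gradient or
  FISTA-type solvers would converge faster for production use.
* The L-curve corner is a discrete Menger-curvature argmax over the solved
  grid; a sparse or under-converged grid can shift the corner. Solves
  should be run to convergence tolerance before trusting it.
* Segment masks come from the analytic LV model, not from image
  segmentation; applying the analysis to non-simulated data would require
  an external LV contouring step.
* The severity grade is monotone in its three inputs but its absolute scale
  is conventional; only orderings should be interpreted.
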