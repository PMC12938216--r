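---
title: "Methods: dual-density spiral real-time phase-contrast MRI in spiralflow"
author: "spiralflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-density spiral real-time phase-contrast MRI in spiralflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

spiralflow implements a complete desk-scale model of free-breathing
real-time phase-contrast MR (RT-PCMR) flow imaging with a dual-density
golden-angle spiral readout, as used on mid-field (0.55T) systems with
moderate gradient hardware. This vignette documents the science behind each
stage, the tunable parameters and their defaults, the numerical choices,
and — importantly — what the synthetic phantom does and does not emulate,
hence what a passing test suite does and does not demonstrate about real
scanner data.

## 1. Trajectory design

### The dual-density spiral

A spiral-out readout covers the k-space disc of radius
$k_{\max} = 1/(2\,\Delta x)$ (cycles/mm, $\Delta x$ the nominal resolution).
The radial distance between neighbouring spiral arms determines the local
sampling density; the Nyquist arm spacing is $1/\mathrm{FOV}$. The
dual-density design samples the first 30% of the readout window at twice
the Nyquist rate and the remaining 70% at 60% of the Nyquist rate: the
oversampled centre carries most of the image energy and supplies the coil
calibration region, while the undersampled periphery buys speed and an
incoherent aliasing pattern that suits compressed-sensing recovery.

"First 30%" is measured along the readout *time* axis. The transition is
smoothed with a cosine taper spanning 5% of the readout so the gradient
waveform has no slope discontinuity (`taper_fraction`, configurable).

### Time-optimal integration

`design_dual_density_spiral()` integrates the Archimedean state
($\theta$, $\dot\theta$, $r$) greedily at a 0.5 µs raster, at each step
taking the largest angular acceleration for which the k-space acceleration
stays within the slew limit ($\gamma s_{\max}$) and the speed within the
amplitude limit ($\gamma g_{\max}$); both limits are enforced on the
*vector* (Euclidean) magnitude, the convention of the variable-density
spiral design literature. The radial pitch is
$dr/d\theta = n / (2\pi\,\mathrm{FOV}\,d(s))$, where $d(s)$ is the density
profile at readout fraction $s$ and $n$ the *design multiplicity*: the
interleaf is designed as one member of a family of $n$ uniformly rotated
copies that would exactly tile k-space at the prescribed density. The
design searches the smallest integer $n$ whose spiral reaches $k_{\max}$
inside the readout window.

Through the density taper the pitch grows by a factor
$d_\mathrm{centre}/d_\mathrm{outer} = 3.3$ within a fraction of a
millisecond, which a purely greedy controller cannot follow without
transiently exceeding the slew limit. The integrator therefore computes the
analytic pitch derivative and brakes (takes the minimal-acceleration root)
whenever the next state would make the slew constraint infeasible. The
resulting waveforms respect both limits at every ADC sample, which the test
suite asserts.

### Two notions of "interleaf count", and the acceleration factor

Two distinct quantities matter:

* `n_arms` — the geometric design multiplicity above (14–15 for the
  0.55T protocol: FOV 300 mm, 2.3 mm, 5.32 ms readout, 26 mT/m, 45 T/m/s).
* `n_full` — the *Nyquist-weighted sampling requirement*: the number of
  Nyquist cells in the k-disc weighted by the prescribed density,
  $N_\mathrm{req} = \mathrm{FOV}^2 \int 2\pi k\, d(k)\, dk$, divided by the
  number of ADC samples one interleaf delivers. For the same protocol this
  is 12.0. It answers "how many interleaves' worth of samples would a fully
  sampled acquisition at this density need", which is the bookkeeping
  behind quoted acceleration factors for variable-density trajectories.

The acceleration factor is `R = n_full / interleaves acquired per
encoding`; with 2 interleaves per velocity encoding the protocol gives
R = 6. The ADC dwell is derived from the receiver bandwidth per pixel
(1116 Hz/px) times the even image matrix (132 for 300/2.3 mm), ≈ 6.79 µs.

### Schedule

Each 44 ms frame holds four 11 ms TRs ordered FC($\theta$), FE($\theta$),
FC($\theta+180°$), FE($\theta+180°$) — flow-compensated and flow-encoded
back-to-back on the same trajectory, the second pair rotated 180°
(counterclockwise positive) to maximize per-frame coverage. The base angle
advances by the golden angle, kept at full precision internally
($360 - 360/\varphi = 137.50776405°$), so that any window of consecutive
frames covers azimuth nearly uniformly (the suite asserts a maximal gap
below 8° over 90 frames). A 4 s scan yields
$\lfloor 4000/44 \rfloor = 90$ frames.

## 2. The pulsatile flow phantom

The phantom stands in for the study's raw subject data, so its defaults
*are* the study conditions of the package:

* geometry: 300 mm FOV, matrix 132 (2.27 mm pixels); an elliptical torso of
  static tissue (magnitude 1); an aorta-like disc (radius 15 mm, peak
  centreline velocity 120 cm/s, 360 ms systole) and an MPA-like disc
  (radius 17 mm, 80 cm/s, 400 ms) with parabolic (Poiseuille) lumen
  profiles, blood magnitude 1.5. These reproduce adult-volunteer scale
  haemodynamics — aortic net flow ≈ 77 mL/beat, peak flow ≈ 425 mL/s,
  Qp/Qs ≈ 0.95.
* rhythm: beat onsets accumulate RR intervals
  $\mathrm{RR} = \overline{\mathrm{RR}}(1 + c_v z)$, $z$ standard normal
  (truncated at 0.4 RR), $\overline{\mathrm{RR}} = 900$ ms, $c_v = 4\%$ —
  the beat-to-beat variability scale reported for real-time acquisitions in
  sinus rhythm. An arrhythmia-like preset replaces the Gaussian model with
  a bimodal short/long mixture (scales 0.62/1.25, 40% short).
* respiration: vessel velocities are modulated by
  $1 + a\,\sin(2\pi t/T_\mathrm{resp})$ with $a = 0.08$,
  $T_\mathrm{resp} = 4$ s, so a 4 s scan spans one full respiratory cycle.
* encoding: the flow-encoded image carries phase $\pi v/\mathrm{VENC}$
  relative to the flow-compensated image (the universal two-point PC
  convention); VENC defaults to 150 cm/s. Velocities beyond VENC wrap,
  exactly as acquired data would.
* concomitant fields: the velocity-encoding waveform pair (a
  first-moment-nulled trapezoid triplet for FC, plus a bipolar for FE,
  built under the gradient limits) produces the lowest-order Maxwell phase
  $\gamma\,(x^2+y^2)\,\Delta\!\int\!G_z^2\,dt / (8 B_0)$ at $B_0=0.55$ T,
  which the phantom *adds* to the rendered FE images (numerically
  integrated) and the velocimetry stage *removes* (closed form) — the two
  paths are implemented independently.
* coils: 6 smooth complex sensitivities (Gaussian lobes on the torso
  perimeter with linear phase ramps), a desk-scale stand-in for the
  18-element arrays of the real system.
* noise: complex Gaussian per k-space sample, calibrated once so the
  vessel-lumen magnitude SNR of a density-compensated gridded frame is
  ≈ 10, qualitatively emulating mid-field SNR. (The study system's true
  SNR is not published; this is a stated assumption.)

Frames are rendered at the frame mid-time; intra-frame motion blur across
the 44 ms window is *not* modelled. There is no relaxation/Bloch
simulation, no in-plane vessel motion, no off-resonance. Consequently,
passing end-to-end tests demonstrate correct *signal processing* —
trajectory, encoding, reconstruction, velocimetry, statistics — not
robustness to scanner physics the phantom omits (off-resonance blurring,
eddy-current background phase, through-plane motion).

The analytic ground truth integrates the prescribed velocity field exactly
(parabolic profile: $Q(t) = v_c(t)\,\pi r^2/2$), at 0.25 ms quadrature;
the configured and analytic Qp/Qs agree to 1e-6.

## 3. NUFFT and density compensation

The non-uniform FFT is Kaiser–Bessel gridding: deapodization (the exact
closed-form kernel transform), zero-padding to an oversampled grid, FFT,
and sparse-matrix interpolation; the adjoint is the exact transpose. With
the default oversampling 2.0 and kernel width 7 the forward operator
matches a dense non-uniform DFT to ~1e-6 relative error; the
reconstruction operator uses oversampling 1.45 and width 5 (the 132-pixel
matrix then lands on a fast 192-point grid), trading ~1e-4 accuracy for a
30% faster FFT — well below the noise floor of any simulated acquisition.
The simulation operator deliberately uses the high-accuracy parameters so
simulation and reconstruction never share the same discrete operator.

Density compensation uses the Pipe–Menon fixed point
$w \leftarrow w / (C^\top C w)$ evaluated through the gridding
interpolator (20 iterations). It is positive by construction, splits
weight between coincident samples instead of diverging, and reproduces the
analytic Archimedean cell-area law ($w \propto k/d(k)$), which the suite
checks against uniform and two-zone spirals. A Voronoi tessellation would
be the classical alternative; the fixed point was chosen because it needs
no computational geometry and handles duplicates natively.

## 4. ESPIRiT coil maps

Sensitivities are estimated from the data themselves: all FC readouts
(pooled over frames — 2 × 90 interleaves cover k-space densely) are
gridded with density compensation into a time-averaged image; its central
24×24 k-space is the calibration region. Sliding 6×6 windows form the
calibration (block-Hankel) matrix; right singular vectors above
`sigma_thresh` (default 0.02 relative) span the local-kernel signal space;
mapping them to image space (explicit small DFT) and eigendecomposing the
resulting per-pixel operator yields the sensitivity vector as the dominant
eigenvector (conjugated, phase-referenced to coil 1 — which also removes
the SVD sign/phase ambiguity and makes the estimate deterministic).
Pixels whose leading eigenvalue falls below 0.9 (outside the coil-supported
object) fall back to the RSS-normalized gridded average, and all maps are
unit-RSS. On noise-free phantom data the estimate correlates with the
generating maps above 0.99 per coil.

## 5. CS-SENSE reconstruction

Each encoding is reconstructed independently (the acquisition gives no
coupling between FC and FE) by solving

$$\hat u = \arg\min_u \tfrac12 \lVert F_\Omega S u - d \rVert_2^2
  + \lambda_s \lVert W_{xy} u \rVert_1
  + \lambda_t \lVert W_t u \rVert_1$$

with $F_\Omega$ the per-frame NUFFT on that frame's two interleaves, $S$
the ESPIRiT maps, and $W_{xy}$, $W_t$ non-decimated (shift-invariant)
wavelet transforms along space and time.

* **Transforms.** Undecimated à-trous filter banks with orthonormal QMF
  pairs scaled by $1/\sqrt2$ per level, making each pyramid a Parseval
  tight frame (`nwt_inverse(nwt_forward(x)) == x` to 1e-10; with both
  pyramids stacked the frame constant is 2). Defaults: Daubechies-2
  spatially (2 levels), Haar temporally (2 levels); both configurable.
* **Solver.** FISTA with step $1/(1.02\,L)$, $L$ from power iteration
  (shared between encodings, same trajectory geometry); complex magnitude
  soft-thresholding applied through the tight-frame synthesis
  ($u \leftarrow W^{H}\,\mathrm{soft}(Wu)$, the standard redundant-frame
  proximal surrogate); a monotone safeguard restarts the momentum whenever
  the objective rises, and persistent increases raise an error advising a
  step-size/λ review. Warm start: density-compensated gridding of each
  frame, scaled by a one-step least-squares line search.
* **Regularization scale.** λ is dimensionless: the proximal threshold per
  iteration equals $\lambda \cdot \max|u_\mathrm{gridding}|$, so values
  transfer across data scalings, coil counts and trajectory norms.
  Defaults $\lambda_s$ = 2e-3, $\lambda_t$ = 1e-2 were tuned visually and
  quantitatively on a single seeded phantom dataset and then frozen for
  every other dataset, test and seed — mirroring the single-dataset tuning
  protocol of inline clinical reconstructions. Temporal regularization
  does most of the work at R = 6; spatial regularization mainly suppresses
  residual swirl artefacts.
* **Stopping.** Relative objective change below 1e-5 or 40 iterations
  (default). The end-to-end suite caps at 32 iterations (tolerance 2e-5), where the flow
  quantities of interest have long converged even though the objective
  tail has not; reconstruction of the 132×132×90 dual-encoding dataset
  then takes a few minutes on one CPU.

## 6. Velocimetry

Phase differences use the magnitude-robust conjugate product
$\Delta\varphi = \arg(\mathrm{FE}\cdot\overline{\mathrm{FC}})$; pixels with
vanishing magnitude get phase 0 and a low-confidence flag. The Maxwell
correction subtracts the closed-form lowest-order concomitant phase of the
encoding waveform pair (transverse slice; only the $G_z^2$ self-term, the
in-plane spiral gradients being identical between encodings); it scales as
$1/B_0$ and vanishes at isocenter. Velocity is $v = \mathrm{VENC}\,
\Delta\varphi/\pi$. Unwrapping is temporal-only: along each pixel's time
course, jumps exceeding VENC are folded back by the integer multiple of
$2\,\mathrm{VENC}$ that minimizes the jump — idempotent, and appropriate
for real-time series where the temporal neighbour is the reliable
reference; spatial unwrapping is not attempted. Background (eddy-current)
phase correction is deliberately not implemented; the static-tissue bias
is *reported* by the tests (< 1 cm/s on noise-free data after Maxwell
correction), not silently removed.

## 7. Flow quantification

Flow curves are ROI sums, $q(t) = \sum_{p\in\mathrm{mask}} v_p(t)\,A_p$,
with the exact unit chain 1 cm/s · 1 mm² = 0.01 mL/s. Beats are windows
between consecutive triggers (the phantom's own onsets, or an external
list); without triggers, onsets are detected on the 3-frame-smoothed curve
as the last near-baseline frame before each upward crossing of a low
threshold (25% of the curve range), with a 350 ms refractory period —
accurate to one frame on phantom-like curves, including the bimodal
arrhythmia fixture. Only complete beats enter the statistics. Per beat:
net flow is the trapezoidal integral of $q$ over the window (with the
curve interpolated to the window edges), peak flow rate the maximum of
$q$, peak velocity the single-pixel ROI maximum per frame (default; a
percentile option exists because clinical software may smooth), RR the
window length. Beat-to-beat variability is the sample coefficient of
variation $100\,s/\bar x$ (n−1 denominator; the population/sample choice
is not standardized, so it is documented here). Qp/Qs is the ratio of
beat-averaged MPA to aortic net flow. ROIs come from the phantom's known
discs; external data can supply masks, or use the Otsu-threshold +
flood-fill helper, which is explicitly *not* equivalent to clinical
auto-contouring.

## 8. Agreement statistics and blur

Bland–Altman limits of agreement use the exact 1.96 multiplier with the
sample SD, per the convention of method-comparison figures. The ICC is the
two-way random-effects, absolute-agreement, single-measures ICC(2,1)
(Shrout–Fleiss), chosen because two fixed methods measure the same
subjects; ICC(3,1) is available. Its 95% CI uses the standard F-based
interval with Satterthwaite degrees of freedom; the implementation is
verified against an ANOVA mean-squares oracle and an independent reference
implementation. Bands: > 0.9 excellent, 0.6–0.9 good, < 0.6 moderate.
The paired t-test is the classical closed form; an all-zero difference
vector returns p = 1 by convention. The blur metric follows the
no-reference perceptual-blur construction (re-blur with a strong 9-tap
averaging kernel; measure the attenuation of neighbour differences
horizontally and vertically; return the larger normalized attenuation):
0 = sharp, 1 = blurred, with a constant image defined as 1. Its test
surface is ordinal — a generated blur ladder must be strictly ordered —
because absolute values depend on content.

## 9. Problem sizes and determinism

Unit tests run at 32×32 (16×16 for operator-accuracy oracles) with a
small 4-coil phantom; the end-to-end recovery check runs the full study
protocol — 132×132 matrix, 90 frames, 6 coils, R = 6, lumen SNR ≈ 10 —
once, and derives every recovery assertion (net flow within 5%, Qp/Qs
within 0.05, peak-velocity underestimation ≤ 10%, beat-to-beat CV
ordering) from that single reconstruction; the static-bias null test uses
a noise-free 20-frame variant. Every stochastic element (beat onsets,
coils, noise) derives from an integer seed and is bitwise reproducible;
the solver itself has no randomness beyond the seeded power iteration.

## 10. Known limitations

* The phantom's omissions listed in §2 (no off-resonance, no eddy-current
  background phase, no motion) mean the package validates method
  correctness, not scanner robustness; spiral deblurring is out of scope.
* Peak velocity inherits a small negative bias from 44 ms temporal
  sampling of a 360 ms systolic bump (up to ≈ 3.6%) on top of
  regularization smoothing — the same direction reported for in vivo
  real-time acquisitions; the suite only bounds it at 10%.
* The greedy time-optimal integrator is near-optimal but not provably
  optimal through the density taper; its braking heuristic costs a few
  percent of readout efficiency.
* ICC confidence intervals assume the two-way ANOVA model; with n < 10
  beats they are wide and the Qp/Qs ICC in particular is unstable, as is
  well known for ratio quantities with narrow physiological range.
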