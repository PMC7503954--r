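---
title: "Methods: diffuse optical tomography of task-related fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffuse optical tomography of task-related fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`fnirsdot` reconstructs volumetric maps of task-related oxy- (O2Hb) and
deoxyhemoglobin (HHb) concentration changes from continuous-wave fNIRS
recordings: dual-wavelength (690/830 nm) DC light intensities measured by a
prefrontal array of 15 sources and 15 detectors sampled at 39.7365 Hz. The
endpoint of a run is a per-voxel t-score map for each chromophore,
thresholded at t = ±1.65 (the one-sided standard-normal 5% critical value,
uncorrected) and restricted to the region where the array's optical
sensitivity is within a factor of 1000 of its maximum.

Because clinical recordings of this kind are not redistributable, the
package includes a first-class synthetic-data generator with known ground
truth; every pipeline stage is validated against either an analytic oracle
or that ground truth.

# Head model and probe geometry

The head is a regular voxel grid (default 2–4 mm isotropic) with tissue
labels scalp/skull, cerebrospinal fluid (CSF), gray matter, and white
matter, layered from the outer surface inward. A flat slab is used for unit
testing and a hemispheric dome for more head-like runs; both admit the same
finite-difference solver. This replaces subject-specific MRI segmentation
and tetrahedral meshing, which are out of scope: a regular grid makes the
forward model simple, fast, and verifiable against a closed-form solution.

Baseline optical properties (absorption `mu_a`, reduced scattering
`mu_s_prime`, refractive index 1.4) are pinned per tissue and wavelength in
`tissue_optics()` from published compilations of adult head optics. The CSF
reduced scattering is set to the diffusion-adjusted effective value
(0.3 mm⁻¹) conventional in diffusion-equation solvers, because true CSF
scattering is too low for the diffusion approximation to hold.

Digitized optode positions are co-registered to the model frame by a
three-point rigid fiducial alignment (nasion, left/right pre-auricula)
using the closed-form Procrustes/Kabsch estimator: centroid removal,
rotation from the SVD of the cross-covariance with determinant +1, no
scaling. The estimator is exact for congruent triangles and least-squares
otherwise. Optodes are then snapped to the nearest surface voxel center
(scalp coupling); snapping, unlike the rigid transform, changes
source–detector separations, so channel distances are recomputed at that
point. Channels are all source–detector pairs with separations in
10–45 mm.

# Forward model

Light propagation is modeled by the continuous-wave photon diffusion
equation

$$-\nabla\!\cdot\!\big(D\,\nabla\Phi\big) + \mu_a\,\Phi = q_0,\qquad
D = \frac{1}{3(\mu_a + \mu_s')}$$

discretized with a 7-point finite-difference stencil, harmonic-mean
diffusion coefficients at tissue interfaces, and Robin (partial-current)
boundary conditions with the internal-reflection parameter derived from the
tissue/air refractive-index mismatch. Sources are isotropic point sources
embedded one transport mean free path (1/`mu_s_prime`) below the surface.
The resulting system is symmetric positive definite and is solved by
Jacobi-preconditioned conjugate gradients to a relative residual of 1e-10
(a sparse Cholesky path exists as an option; CG is faster on 3-D grids at
this conditioning).

On a homogeneous 2 mm phantom the solver matches the analytic
extrapolated-boundary Green's function of the semi-infinite medium within
10% over 10–40 mm source–detector separations; this is enforced by tests.
At coarser resolution (4 mm), near-optode voxels carry larger quadrature
error, which is why oracle comparisons are made at 2 mm and mid-channel.

Channel sensitivity uses the Rytov/adjoint construction

$$J[\mathrm{ch}, v] \;=\; \frac{\Phi_s(v)\,\Phi_d(v)\,V_{\mathrm{vox}}}{A_{sd}},$$

with the detector fluence obtained by reciprocity (solving with the
detector as a source halves the solve count) and $A_{sd}$ the unperturbed
channel amplitude. Rows map voxel absorption changes (mm⁻¹) to
optical-density changes on the natural-log scale; the Rytov (log-intensity)
linearization is chosen because the whole pipeline works in optical
density. The adjoint rows agree with brute-force single-voxel `mu_a`
perturbations within 5% on well-resolved masked voxels (tested).

The sensitivity mask aggregates |J| over channels and averages over the two
wavelengths; voxels within `attenuation_factor` (default 1000) of the
maximum aggregate sensitivity are retained. Whether the aggregation should
run over channels, wavelengths, or both is genuinely open; this package
aggregates over both, which makes the mask chromophore-neutral.

# Task protocols

Three designs are built as event tables:

* **SWG** (silent word generation, block design): 60 s rest, then five
  blocks of three contiguous 10 s letter slides (stimulation) followed by
  three 10 s nonsense-symbol slides (within-task baseline), then 60 s rest
  (420 s total).
* **SS** (symbol search): 60 s rest, 120 s continuous task, 60 s rest.
* **DS backward** (digit span): same shape, but the task length depends on
  when the participant fails two consecutive sequences, so the measured
  duration is supplied by the caller; synthetic runs default to 180 s.

The GLM's assumed neuronal response is the binary stimulation indicator
(`design_vector`); the pre-task rest minute is the baseline window for the
variability statistic.

# Synthetic recordings

`simulate_recording()` composes, in order:

1. **Activation**: a sphere (default radius 10 mm) of gray-matter voxels
   around a chosen center. Its O2Hb time course is the stimulation
   indicator convolved with a canonical double-gamma HRF (peak 6 s,
   undershoot 16 s, ratio 1/6, 32 s support, peak-normalized), scaled to
   `peak_o2hb` (default +1 µM); HHb is the same course scaled by
   −1/`hhb_ratio` (default 2.5, inside the 2–3× band characteristic of a
   neurovascular response). The sphere is the package's own choice — no
   activation geometry is prescribed by the problem.
2. **Physiological noise**: global sinusoids at cardiac (1.1 Hz),
   respiratory (0.25 Hz) and Mayer-wave (0.1 Hz) frequencies with seeded
   random phases, plus random-walk drift, all expressed as gray-matter
   chromophore oscillations; extracranial interference is a slow + cardiac
   mixture confined to scalp voxels. Amplitudes (0.6/0.3/0.25 µM, drift
   0.03 µM·s^-1/2^, scalp gain 0.4 µM) were calibrated once so that
   band-pass-filtered channel-level hemoglobin noise has SD ≈ 0.1–0.3 µM,
   a plausible background for signals of a few µM; they are configuration
   defaults, not empirical claims.
3. **Optics**: chromophores map to per-wavelength Δ`mu_a` through the
   pinned extinction table (shared with the inverse path, so round trips
   are exact by construction), then to channel ΔOD through the Jacobian,
   then to intensities $I = A_{sd}\,e^{-\Delta OD}(1+\epsilon)$ with
   multiplicative measurement noise; motion spikes and step shifts are
   injected in the OD domain, identically at both wavelengths of a
   channel.

What the generator does *not* emulate: spatially heterogeneous vascular
territories, serially correlated (1/f) noise, task-correlated motion or
systemic responses, and optode-specific coupling losses. Passing end-to-end
tests therefore demonstrates internal consistency of the method under
plausible noise, not performance on real patients.

# Preprocessing

Intensities are normalized by their temporal mean and converted to optical
density, OD = −ln(I/Ī), making the result invariant to per-channel gain.
Motion artifacts are detected per channel from first differences exceeding
5 robust SDs (MAD), dilated by 0.3 s; persistent steps are re-leveled by
flank-median matching and flagged spans replaced by cubic-spline
interpolation — unflagged samples are never altered, and channels with more
than half their samples flagged are marked bad and excluded. The detection
threshold trades false positives (< 1% of clean samples altered, tested)
against sensitivity to 0.5 OD spikes (≥ 5× error reduction, tested). The
spike-plus-spline scheme is the package's choice of a transparent,
testable corrector.

Band-pass filtering is a 4th-order Butterworth (0.01–0.3 Hz) applied
forward and backward (zero net phase). At 39.7 Hz sampling the low edge
sits at a normalized frequency of 5·10⁻⁴, where a single transfer-function
realization is numerically unstable, so the filter is factored into
second-order sections obtained by bilinear transform of the analog
prototype, with per-section gain normalization. Series are reflect-padded
by three low-edge periods and trimmed; recordings shorter than three
settling lengths of the low edge (≈ 48 s) are rejected.

After filtering, series are decimated to ≈ 4 Hz (the retained band ends at
0.3 Hz, far below the decimated Nyquist), which cuts inversion and GLM cost
by an order of magnitude without affecting the statistics.

Channel-space hemoglobin for quality inspection uses the modified
Beer–Lambert law with the pinned extinction matrix and differential
pathlength factors 6.0 (690 nm) / 5.8 (830 nm).

# Tomographic inversion and unmixing

Per wavelength and time sample, voxel absorption changes are the
minimum-norm Tikhonov solution

$$x = J^\top\!\left(JJ^\top + \alpha\,\frac{\mathrm{tr}(JJ^\top)}{n_{ch}} I\right)^{-1} y,$$

with α = 0.01 by default; the factorization is computed once and reused
across samples, and time samples are inverted independently (no temporal
coupling). Regularization is spatially uniform — the minimal reading of an
energy-minimization (minimum-norm) inverse; no depth weighting is applied
by default. The trace scaling makes α dimensionless, so the default does
not depend on grid resolution or channel count. Voxels outside the
sensitivity mask are identically zero. Spectral unmixing solves the 2×2
extinction system per voxel and sample; with the pinned matrix (condition
number ≈ 3) this is exact to numerical precision.

Minimum-norm reconstructions on coarse grids underestimate focal amplitudes
severely (partial volume and regularization bias); location and sign are
the reliable outputs, which is why inference is based on t-statistics
rather than reconstructed amplitudes.

# Statistics

**GLM (block designs).** Each voxel's chromophore course is regressed on
the expected response (stimulation indicator ⊗ canonical HRF, band-limited
identically to the data) plus intercept and linear drift. The flanking rest
minutes are excluded from the fit, so the within-task symbol epochs act as
the implicit baseline; this is one admissible reading of a design in which
the nonsense-symbol slides are the stated baseline condition. Band-pass
filtering leaves far fewer independent samples than time points, so the
effective degrees of freedom are set to n·(2·f_high/fs), floored at 10;
with unfiltered data the classical residual dof applies. Under white noise
the empirical type-I rate at t > 1.65 is within the binomial band around
5% (tested on 10,000 voxels).

**Windowed variability (unstructured tasks).** The SD of each chromophore
is computed in non-overlapping 10 s windows of the pre-task rest minute
(baseline; 6 windows) and of the task (12 windows for a 120 s task), and
the two SD populations are compared by a Welch unequal-variance t statistic
(task − rest). Only the pre-task minute is used as baseline — the post-task
minute may carry response tails. The statistic is exactly invariant to sign
flips and constant offsets: it measures oscillation amplitude, not
direction, and is therefore thresholded one-sidedly (t > 1.65).

**Maps.** Suprathreshold sets are {|t| > 1.65} (GLM) or {t > 1.65}
(variability), uncorrected, inside the sensitivity mask. The spatial
Pearson correlation between the O2Hb and HHb t maps is reported as a
diagnostic: genuine hemodynamic activity drives it strongly negative.

# Numerical and design choices, in brief

* CG tolerance 1e-10; negative fluence roundoff clipped at zero.
* Reciprocity used for detector fluences; verified to < 1e-6 relative.
* Welch rather than pooled t for SD populations (no variance-equality
  assumption across task and rest).
* `attenuation_factor` must be ≥ 1; the value 1 keeps only the
  most-sensitive voxel (boundary case), and values < 1 are rejected.
* Tie-breaks: the first voxel in column-major order wins where argmax ties
  occur (relevant only in degenerate synthetic cases).
* Problem sizes: unit tests use a 96×72×32 mm slab at 4 mm with a 128
  channel array; oracle comparisons a 120×80×60 mm phantom at 2 mm;
  end-to-end recovery 20 seeded runs on a 120×120×60 mm slab at 4 mm.
  These sizes were chosen as the coarsest at which each property is
  well-resolved, keeping the full suite fast.

# Known limitations

* The diffusion approximation is poor in low-scattering CSF and within a
  transport mean free path of sources; the effective-scattering CSF value
  and embedded-source convention are standard mitigations, not fixes.
* Three-point fiducial alignment cannot correct head-shape differences to
  a template; it is a rigid map only.
* Minimum-norm inversion without depth weighting biases reconstructions
  toward superficial voxels; the sensitivity mask limits, but does not
  remove, this effect.
* Effective-dof correction for filtered series is a heuristic
  band-counting argument, calibrated by the white-noise test rather than
  derived from the true residual autocovariance.
* No multiple-comparison correction is applied, by design: maps are
  exploratory single-subject summaries at an uncorrected p < 0.05.
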