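---
title: "Methods: cardiac DTI structural analysis and the synthetic LV phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac DTI structural analysis and the synthetic LV phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

cardioDTI characterizes myocardial microstructure in ex vivo
diffusion-weighted MRI of infarcted, cell-grafted left ventricles. The chain
is: per-voxel diffusion tensor reconstruction; fractional anisotropy (FA) and
mean diffusivity (MD) maps; local cardiac coordinate frames; helix (HA),
transverse (TA), and absolute sheetlet (|E2A|) angle maps; helix-angle
transmurality (HAT) and TA dispersion as alignment summaries; scar and graft
segmentation from a contrast-enhanced (CE) volume; deterministic streamline
tractography; and the group statistics that compare remote, scar and graft
tissue. Because real graft-bearing specimens are not distributable, the
package ships a synthetic left-ventricle phantom whose every voxel has known
tensor, angle, depth and label ground truth; all validation runs against it.

## Tensor estimation

The signal model is the standard monoexponential forward physics,
$S_k = S_0\,\exp(-b_k\, g_k^\top D\, g_k)$. Estimation is ordinary
(unweighted) log-linear least squares on the 7-parameter design
$(\ln S_0, D_{xx}, D_{yy}, D_{zz}, D_{xy}, D_{xz}, D_{yz})$: reproducible,
and exact on noiseless data, which yields the suite's sharpest oracle — on a
noiseless phantom the fitted tensors equal the generating tensors to
floating-point precision. All b0 volumes enter the design, so b0 averaging
is implicit in the LS solution. Weighted or nonlinear variants were
deliberately not implemented; the unweighted fit is the auditable baseline
and the phantom's SNR regime (50 at b0) leaves little bias to correct.

Numerical policy: voxels with any non-positive signal are flagged invalid
and excluded (flag 2, never fatal); negative eigenvalues are clamped to
1e-12 and flagged (flag 1) rather than discarded, so region statistics stay
computable and the flagged fraction remains visible.

## Cardiac frames and angle conventions

The frame is the orthonormal triad (circumferential $\hat c$, outward radial
$\hat r$, longitudinal $\hat z$), with $\hat c = \hat z \times \hat r$. The
long axis defaults to the image z-axis and is configurable. The radial
direction comes from per-slice cavity centroids by default (exact for the
phantom's annular geometry) or from the in-slice gradient of the
transmural-depth field for non-cylindrical walls.

The angle conventions are pinned explicitly, since the literature states
them loosely:

* HA $= \operatorname{atan2}(e_1\cdot\hat z,\; e_1\cdot\hat c)$ — 0° at
  circumferential, +90° at longitudinal (toward the base);
* TA $= \operatorname{atan2}(e_1\cdot\hat r,\; e_1\cdot\hat c)$ — positive
  toward the outward radial;
* $|E2A| = |\operatorname{atan2}(e_2\cdot\hat r,\; e_2\cdot\hat t)|$ with
  $\hat t = \widehat{r\times e_1}$, folded into [0°, 90°].

Eigenvector signs are fixed before angle evaluation: $e_1$ so its
circumferential component is non-negative (tie-break toward $+\hat z$ when
the circumferential component vanishes), $e_2$ so $e_2\cdot\hat r \ge 0$,
$e_3 = e_1 \times e_2$. The operation is idempotent. TA enters its
dispersion summary *signed*; the SD of signed and absolute TA coincide only
for a zero-mean distribution, which holds by construction in the phantom and
approximately in tissue.

Transmural depth is $100\, d_{\text{endo}}/(d_{\text{endo}} +
d_{\text{epi}})$ from dual per-slice Euclidean distance transforms. The raw
transform measures distance to the nearest cavity/exterior voxel *center*,
overshooting the anatomical boundary by about half a voxel on each side, so
a 0.5-voxel surface correction is subtracted. On the default 0.3 mm grid
the corrected TD agrees with the analytic cylinder depth to a median of
well under 1.5 %TD; residual discretization noise remains, which is why the
angle-recovery tests regress fitted HA on the phantom's analytic depth —
regressing on the estimated depth additionally measures TD-map error
(a ~1% errors-in-variables attenuation of the HAT slope), which the suite
tests separately.

## Structural summaries

HAT is the OLS slope of per-voxel HA on TD in °/%TD. The transmural window
retains TD in [15%, 75%] by default — border bins suffer partial-volume and
frame-degeneracy effects, and grafts localize to the mid-myocardium — and
the window is a uniform config parameter. The fit uses per-voxel pairs; the
15% bin profile is kept for plotting, with a switch to fit the bin means
instead. Bin edges are half-open at the low edge with the final bin closed.
Handedness classes are right-handed (+30°, +90°], circumferential
[−30°, +30°], left-handed [−90°, −30°); the ±30° boundaries go to the
circumferential class — a deterministic, documented tie-break. Circular
statistics are not used: HA and TA live in (−90°, 90°] and wrap-around is
negligible away from ±90°; values within 5° of ±90° trigger a warning.

## Segmentation

Remote tissue is a configurable angular sector of the wall (default
210°–330°, a simplified stand-in for the two standard mid-cavity reference
segments). Scar is every wall voxel whose CE intensity exceeds the remote
mean plus 5 remote sample SDs (n−1); the threshold and remote statistics are
recorded as provenance. The graft is grown from user-supplied seeds by
26-connected flood fill accepting voxels within a fixed tolerance of the
running region mean — the published description of the region-growing step
is not algorithmic, so the criterion is pinned here and its seeds and
tolerance recorded; growth is provably monotone in the tolerance. Graft
voxels are carved out of the scar label. No boundary erosion is applied by
default.

## Tractography

Deterministic bidirectional Euler integration of $e_1$ at a fixed step
(default 0.15 mm, half a voxel), with trilinear interpolation of the six
tensor components and eigendecomposition at each sample point, and per-step
sign re-orientation against the previous direction. Stops: FA below 0.1,
turning above 60° per step, mask exit, or a length cap; for graft runs the
cap is the seed-ROI bounding-box diagonal — the least restrictive reading of
limiting tracts to the ROI's maximum length. The reference tracking
parameters used with external software are unpublished, so these defaults
are conventional and config-exposed. Streamlines round-trip through TCK
(MRtrix) files; TCK was chosen over TRK because it is simpler and natively
world-coordinate.

## Statistics

Group comparisons use the classical one-way ANOVA with Tukey HSD post-hoc
(the between/within sums of squares are reported alongside F), a paired
t-test for scar-vs-remote within a cohort, Bland-Altman agreement
(bias = mean(DTI − reference), limits ±1.96 SD), and Pearson correlation.
Two $R^2$ flavours are returned: the squared correlation of the fitted
line, and the variance explained by the identity line
$1 - \mathrm{SS}(y-x)/\mathrm{SS}(y-\bar y)$. They differ whenever the two
methods disagree in bias or scale, which is why a reported method-agreement
$R^2$ need not equal $r^2$; both are provided rather than adjudicated.
Cohort timepoints are pooled by default; the significance threshold is 0.05
with no correction beyond Tukey.

# The phantom: what it emulates and what it does not

The generator produces a stack of concentric annuli (a straight cylinder,
long axis = z) at 0.3 mm isotropic, default 64 × 64 × 16; the acquisition is
b = 0 and 700 s/mm² with 5 b0 volumes and 30 diffusion directions from a
seeded electrostatic-repulsion scheme written to FSL-style bval/bvec files.
The cylinder, rather than a prolate spheroid, is a deliberate choice: it
makes the circumferential and radial directions analytic, so the
coordinate-frame code is testable against closed forms.

The helix angle varies linearly with transmural depth from +60° (endo) to
−60° (epi) — conventional mammalian values, parameterized because the true
range for the target species is not established; the linear rule lets HAT
recovery be tested against arbitrary known slopes. The transverse angle is
drawn per voxel from a zero-mean normal with SD 10° by default. The primary
eigenvector is built as
$e_1 \propto \hat c + \tan(\mathrm{HA})\,\hat z + \tan(\mathrm{TA})\,\hat r$,
chosen so that *both* atan2 conventions above recover the injected angles
exactly (composing two sequential rotations instead distorts the recovered
TA by a factor 1/cos HA). The secondary eigenvector is placed in the wall
tangent plane ($e_2 = \widehat{\hat r \times e_1}$), so |E2A| truth is 0°.

Region tensors are assigned from three eigenvalue triples chosen to
reproduce the field's reported group means — remote FA ≈ 0.26 / MD ≈ 0.93 ×
10⁻³ mm²/s, scar FA ≈ 0.14 / MD ≈ 1.62 × 10⁻³, graft FA ≈ 0.22 / MD ≈ 1.1 ×
10⁻³ — with λ₂ > λ₃ strictly so $e_2$ is well-defined. At these modest
λ₂−λ₃ gaps the secondary eigenvector is noise-limited: at SNR 50 the median
recovered |E2A| sits near 5° even though truth is 0°, a genuine property of
the conditions, frozen into the tests from a pre-build Monte-Carlo.

Noise is Rician — the magnitude-MRI physical default, applied as
$\sqrt{(S+n_1)^2 + n_2^2}$ with $n_i \sim N(0, S_0/\mathrm{SNR}_{b0})$ —
with SNR 50 at b0 by default (a long ex vivo acquisition; the source
acquisition's SNR is unreported). Background voxels carry the pure noise
floor and are excluded by masks. The CE volume is Gaussian per region with
scar 8 remote-SDs above remote and the graft pocket attenuated back to the
remote level, so the 5-SD rule and the region grower have honest but
non-trivial recovery tasks.

Deliberately not modelled: EPI distortion, eddy currents, relaxation,
partial-volume mixtures, inversion-recovery CE physics, prolate geometry,
and registration estimation (the CE-to-DWI affine is an input, identity for
phantom runs). Passing tests therefore demonstrate correctness of the
estimators and conventions under realistic noise and geometry
discretization — not robustness to acquisition artifacts or registration
error in real scans.

# Problem sizes and determinism

The test suite uses a 32 × 32 × 8 phantom for unit tests and the full
64 × 64 × 16 grid (35 volumes, ~24k wall voxels) for end-to-end recovery,
with 10 seeded replicates for the noisy angle-recovery bands; these sizes
keep every suite comfortably within a few minutes on one CPU while leaving
thousands of voxels per region for stable statistics. All randomness —
direction scheme, TA dispersion, DWI noise, CE draw — derives from the
single phantom seed via fixed offsets, and every RNG use restores the
caller's RNG state, so identical specs give bitwise-identical volumes,
labels and metric tables on re-run.

# Known limitations

* The unweighted LLS estimator is mildly biased at low SNR; no RESTORE or
  free-water variants.
* TD and frames are per-slice constructs; strongly oblique or non-annular
  walls need the gradient-based radial method and isotropic in-plane voxels.
* Linear-SD angle summaries ignore wrap-around within 5° of ±90°.
* The AHA-sector remote definition is a mid-cavity simplification anchored
  at a configurable reference angle; apex/base segment logic is out of
  scope.
* Histology comparison enters as plain angle tables; no image processing of
  stained sections is provided.
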