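# cardioDTI

Structural analysis of ex vivo cardiac diffusion tensor MRI for infarcted,
cell-grafted hearts — aimed at researchers quantifying whether engrafted
cardiomyocytes organize into aligned, anisotropic tissue.

Stem-cell grafts implanted into myocardial scar cannot be distinguished from
host tissue by eye in conventional MRI. Two imaging handles make them
measurable: contrast-enhanced (CE) imaging, where scar hyperenhances while
graft remains attenuated, and diffusion tensor imaging (DTI), where the
per-voxel diffusion tensor reports local myocyte organization. This package
implements the full chain from raw diffusion-weighted volumes to the scalar
biomarkers used to compare remote myocardium, scar, and graft:

* **Tensor reconstruction** — log-linear least squares on
  ln S = ln S₀ − b gᵀDg, with eigen-system, fractional anisotropy
  FA = √(3/2)·‖λ − λ̄‖/‖λ‖ and mean diffusivity MD = (λ₁+λ₂+λ₃)/3.
* **Cardiac angle maps** — local (circumferential ĉ, radial r̂,
  longitudinal ẑ) frames; helix angle HA = atan2(e₁·ẑ, e₁·ĉ), transverse
  angle TA = atan2(e₁·r̂, e₁·ĉ), sheetlet angle |E2A|; transmural depth from
  dual distance transforms.
* **Structural summaries** — helix-angle transmurality (HAT, the OLS slope
  of HA on transmural depth in °/%TD, fitted over the retained 15–75 %
  window), right-handed / circumferential / left-handed voxel fractions
  (±30° class bounds), and the SD of TA as a myocyte-alignment marker.
* **Segmentation** — remote sector definition, scar by the
  mean + 5·SD remote-intensity rule, graft by seeded 26-connected region
  growing inside the hyperenhanced territory.
* **Tractography** — deterministic bidirectional Euler tracking of e₁ with
  FA / turning-angle / mask / ROI-length stops, TCK file round trip.
* **Statistics** — one-way ANOVA with Tukey HSD, paired t-tests,
  Bland-Altman agreement, Pearson r with both R² flavours.
* **Synthetic LV phantom** — an annular left ventricle with a linear
  +60°→−60° transmural helix rule, per-region tensors, Rician noise, and a
  matched CE volume, providing exact ground truth for every stage.

## Worked example

Simulate the default phantom (64 × 64 × 16 voxels at 0.3 mm, b = 0 and
700 s/mm², 5 b0 + 30 directions, SNR 50) and run the full pipeline:

```r
library(cardioDTI)

ph  <- simulatePhantom(phantomSpec(seed = 42))
res <- runPhantomPipeline(ph, "out")
print(res$summary)
```

```
  region metric    n         mean           sd          sem
1 remote     FA 8160 0.2676862203 2.036067e-02 2.253964e-04
2 remote     MD 8160 0.0009301136 1.628721e-05 1.803025e-07
3   scar     FA 6582 0.1462649940 1.869452e-02 2.304281e-04
4   scar     MD 6582 0.0016197605 2.068949e-05 2.550180e-07
5  graft     FA 1561 0.2285982492 1.932398e-02 4.890971e-04
6  graft     MD 1561 0.0011003549 1.695065e-05 4.290274e-07
```

The three CE-derived regions recover their generating tensors: remote tissue
is anisotropic (FA ≈ 0.27) with MD ≈ 0.93 × 10⁻³ mm²/s, scar is nearly
isotropic (FA ≈ 0.15) with elevated MD ≈ 1.62 × 10⁻³, and the graft pocket
sits in between (FA ≈ 0.23, MD ≈ 1.10 × 10⁻³) — the signature of grafted
myocytes forming organized but not fully mature tissue. The helix-angle
fit over the wall,

```r
fitHAT(res$angles, ph@tdTrue, ph@wall)
#> HAT: slope -1.196 deg/%TD, intercept 59.8 deg, r = -0.969 (n = 13888)
```

recovers the phantom's generating transmurality of −1.2 °/%TD (helix angle
falling linearly from +60° at the endocardium to −60° at the epicardium),
and `taAlignment(res$angles, regionMask(res$labels, "remote"))` returns the
injected 10° transverse-angle dispersion to within half a degree. Dice
overlap of the 5-SD scar mask and the region-grown graft against ground
truth both exceed 0.99 under the default CE contrast.

`writePhantom(ph, dir)` exports the acquisition as NIfTI + FSL bval/bvec +
truth TSV, and `inst/scripts/cardiodti.R` wraps the simulate / fit /
pipeline stages for shell use.

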