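---
title: "Volumetric quantification of nuclear fluorescence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric quantification of nuclear fluorescence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

A nucleus expressing a fluorescently tagged protein at intranuclear
concentration $c$ (a.u./µm³) and occupying volume $V$ (µm³) emits a total
signal $T = cV$. Classifying cells by concentration rather than brightness
requires estimating both $T$ and $V$ per nucleus from a confocal z-stack —
a measurement confounded by out-of-focus blur, photon noise, background
fluorescence, and nuclei cut by the stack borders. `nucquant` implements
the full measurement chain as testable code:

1. **simulate** — ground-truth scenes of ellipsoidal nuclei rendered into
   realistic stacks (so every later stage can be validated against known
   truth);
2. **deconvolve** — depth-bricked maximum-likelihood (Richardson–Lucy)
   restoration;
3. **segment** — iso-surface thresholding at the background level with
   truncation/merge quality filters;
4. **measure** — per-nucleus volume integrals and volumes, including the
   fast ellipsoid approximation $V \approx \tfrac23 A_{\max} h$;
5. **stats** — constant-concentration fits, population concentration
   ratios, DNA-content (ploidy) peak calling, Spearman correlations, and
   gel densitometry.

# The simulator

## What it emulates

Scenes emulate ex-vivo tissue imaged on a confocal with a 40×/1.30 oil
objective: fields tens to hundreds of µm wide and 30 µm deep, nuclei of
distinct cell types, each type holding a fixed intranuclear concentration.
Nuclei are ellipsoids with mild flattening (z semi-axis 60–90% of the
largest) and a free in-plane rotation; they are placed by rejection
sampling with a ≥1 µm surface gap and a 1.5 µm face margin, so truth
nuclei are never truncated. When no field size is given, the lateral field
is scaled so summed bounding-sphere volumes fill ≤25% of the field — a
tissue-like nuclear density that also bounds placement failures.

Image formation is: sub-voxel voxelization of each ellipsoid (3×3×3
supersampling of surface voxels, keeping volume bias well under 1%), plus
a diffuse background floor, convolved with the depth-matched PSF brick,
then Poisson photon noise at `photon_scale` (default 40 expected photons
per a.u.), additive Gaussian read noise (σ = 0.05 a.u.) and a detector
offset (0.1 a.u.). Defaults put a dim cell type (1 a.u./µm³) at ~40
photons/voxel over a ~6-photon floor — a deliberately unfavourable,
YFP-like regime. All randomness flows from one integer seed; rendering is
bit-reproducible.

## What it does not emulate

No photobleaching, spectral bleed-through, vascular/tissue texture,
scattering inhomogeneity, or drift. Passing tests therefore demonstrate
that the *algorithms* are unbiased under the stated detector model, not
that any given real tissue meets that model.

## Preset parameter provenance

The 5:1 neuron/glia concentration contrast is the quantity of scientific
interest; absolute volumes (neuron 520 µm³, glia 150 µm³, chondrocyte-like
G1 volume 200 µm³) are plausible placeholders chosen once, since only
ratios and peak positions enter the statistics. The cycling population
uses G1/S/G2 fractions 0.55/0.15/0.30 and a 5% CV multiplicative staining
factor; total DNA signal tracks DNA content (not nuclear volume), as for a
stoichiometric stain, while volume scales with content — so integrated
totals form peaks at ratio 2 and per-nucleus DNA concentration stays
roughly constant.

# Optics

## Theoretical PSF

The confocal PSF is approximated as a separable 3-D Gaussian with
$\sigma_{xy} = 0.30\,\lambda/\mathrm{NA}$ and
$\sigma_z = 0.80\,\lambda n/\mathrm{NA}^2$ (λ = 527 nm, NA = 1.30,
n = 1.515 by default, giving $\sigma_{xy} \approx 0.12$ µm and
$\sigma_z \approx 0.38$ µm). The two constants are package conventions,
set between the widefield diffraction limit and the blur of a real pinhole
at typical openings. Because the pipeline integrates over whole nuclei,
unit kernel mass matters far more than tail shape; the Gaussian model is
deliberately swappable. Depth-dependent spherical aberration is a linear
axial inflation, $\sigma_z(d) = \sigma_z(1 + \beta d)$ with β = 0.02/µm.
Lateral sampling coarser than $2\sigma_{xy}$ is rejected with an error
rather than silently aliasing the kernel.

## Depth bricks

The stack depth is partitioned into contiguous "bricks", each deconvolved
with the PSF evaluated at its mid-depth: 6 bricks in the dense mode, 2 in
the sparse one, 1 for a depth-invariant PSF. The count 6 is an
implementation convention (commercial packages do not document theirs).
Slabs are padded by the kernel half-width and blended by linear feathering
across brick boundaries so restored stacks have no seams.

## Maximum-likelihood deconvolution

Restoration maximizes the Poisson likelihood of
$y \sim \mathrm{Pois}(Hx + b)$ by multiplicative Richardson–Lucy updates
with border renormalization ($H^\top 1$) and an SNR-tied damping,

$$x \leftarrow x\left(\frac{H^\top\!\big(y/(Hx+b)\big)}{H^\top 1}\right)^{\gamma},
\qquad \gamma = \frac{1}{1 + \mathrm{snr}^{-2}},$$

so the damping term is proportional to $1/\mathrm{snr}^2$ and vanishes at
the data-consistent fixed point — with identity optics the input is
reproduced exactly, and flux is conserved. An additive Tikhonov penalty in
the update denominator was rejected because it biases the fixed point and
breaks both properties. Iterations stop when the relative L2 change
between successive estimates drops below the quality-change threshold
(default 0.1%), or at `max_iterations` (default 40, in line with common
commercial defaults). The cap matters: at the default photon budget the
0.1% rule alone would run past 200 iterations, where RL's well-known noise
amplification erodes the interior intensity plateaus that the volume
estimator relies on (measured on simulations: −3% volume bias at 40–60
iterations, −8% at 150). Early stopping is the standard practical
regularizer for photon-limited RL; hitting the cap is recorded as a
warning in provenance, never silently.

# Segmentation and measurement

## Threshold

The iso-surface is drawn "at the background": the threshold is the mode of
the voxel histogram (kernel-density argmax) plus 3 scaled MADs. On a
deconvolved stack the flat background has already been removed, so the
pipeline uses 3 × the raw-stack background MAD as the level — the same
rule expressed in the restored intensity scale.

## Filters

Components below `min_volume` (default 30 µm³) are dropped as noise;
components touching any stack face are dropped as truncated (their volume
integral would be incomplete); components larger than 2.5× the robust
median candidate volume are dropped as merged/under-segmented. There is no
watershed splitting — merged objects are rejected, not repaired. Holes are
filled per z-slice (not in 3-D) to avoid sealing the gap between
vertically adjacent nuclei. 26-connectivity is the default; 6-connectivity
is available.

## Totals and volumes

`total_signal` is the background-corrected voxel sum times the voxel
volume, so `concentration = total_signal / volume` is in the same
a.u./µm³ units as the simulator truth. Whether the iso-level, the
background, or nothing is subtracted before integration is exposed as
configuration (`background`, `subtract_background`); the default
subtracts the residual background, making totals robust to blur and
offset.

Volume uses the **half-plateau rule** by default: within each label, count
voxels at or above half that label's median intensity. The mid-height
point of a blurred step sits at the true edge location, so this count is
unbiased, whereas counting *every* voxel inside a background-level
iso-surface adds roughly half a voxel shell all around (+8–17% measured on
simulated nuclei, worse for small nuclei — which would also fake a
negative concentration–volume trend). The literal count is available as
`volume_method = "voxel_count"`.

The fast ellipsoid approximation
$V \approx \tfrac23 A_{\max} h$ (largest single-slice cross-section ×
z-extent) is exact for axis-aligned ellipsoids, ≈−33% for a cube, and
overestimates for ellipsoids tilted out of the imaging plane; the package
reports it alongside the voxel measure with a `fast_volume` QC flag rather
than hiding the discrepancy.

# Statistics

* **Constant-concentration fit** — through-origin least squares
  ($\hat c = \sum TV / \sum V^2$) formalizes the radial iso-concentration
  picture; the uncentered $R^2$, a free-intercept fit (diagnostic), a
  seeded bootstrap CI (2000 resamples), and the Spearman correlation
  between per-cell concentration and volume (≈0 under constancy, ≈1 for
  $T \propto V^2$) are reported together.
* **Concentration ratio** — ratio of group mean concentrations with a
  seeded bootstrap CI, reported in both orientations and as a percentage.
  "Average nuclear signal" is taken as total/volume (not mean voxel
  intensity); both are computable, but concentration is the quantity the
  iso-contour representation makes comparable across cell sizes.
* **Ploidy peaks** — Gaussian KDE with Silverman's bandwidth (the paper
  behind the validation shows a histogram but names no binning), local
  maxima above a 5%-of-max prominence floor, positions normalized by the
  lowest peak; normalization is idempotent and scale-invariant. Bootstrap
  CI over nuclei. Fewer than two peaks is a warning, not an error.
* **Spearman correlation** — rho from mid-ranks. Two-sided p: full
  permutation enumeration for n ≤ 8, seeded Monte-Carlo permutation for
  8 < n ≤ 50 (full enumeration is n! and infeasible there), t
  approximation above. No multiple-testing correction is applied — the
  readout is descriptive across a handful of channels — and this is
  flagged here deliberately.
* **Densitometry** — rectangle volumes with local background = mean of a
  2-pixel frame around each rectangle (frame width is a convention;
  commercial kernels are proprietary); per-lane normalization by a
  loading-control rectangle; fold changes against a named reference lane.
  Adding a constant to the whole gel image cancels exactly.

# Numerical and design choices

* **Test geometry.** The package's own simulations run at 0.2/0.2/0.4 µm
  voxels over fields auto-sized to the population (e.g. ~150 µm lateral
  for 300 nuclei, ~65 µm for 48), i.e. half the acquisition-grade sampling
  rate that remains the `run_config()` default for real data. At this
  geometry the smallest simulated nuclei still span ≥15 voxels per axis,
  and the two headline simulations complete in roughly 6 and 1 minutes on
  one CPU.
* **Determinism.** A single integer seed drives scene sampling; rendering
  and every bootstrap take explicit seeds derived from it. Identical
  configurations produce byte-identical statistics output. RNG state of
  the calling session is always restored.
* **Degenerate inputs.** Constant images are a background-estimation
  error; all-equal volumes disable the constancy diagnostic with a
  warning but keep the fit; empty segmentations warn and return empty
  tables; constant variables make rho an error.
* **TIFF storage.** The `tiff` container is written as 32-bit integer
  samples with a recorded intensity scale (sidecar JSON also carries voxel
  size, shape, channels); round-trip relative error is below 1e-9. Voxel
  sizes are never defaulted silently — reading a TIFF without metadata and
  without an explicit `sampling` argument is an error.

# Known limitations

* The Gaussian PSF has no Airy side-lobes or vectorial asymmetry; bias
  from realistic tails is untested (but bounded by unit kernel mass).
* Touching nuclei are rejected, not split; heavily clumped tissue would
  lose many cells to the `merged` filter.
* The half-plateau volume rule assumes nuclei are filled (roughly uniform
  interiors); it would under-measure strongly textured or hollow objects.
* Permutation p-values between n = 9 and 50 are Monte-Carlo estimates
  (20000 draws by default via `n_perm`), not exact.
* The simulator's noise model is stationary; detector artefacts (stripes,
  flicker, saturation) are out of scope.
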