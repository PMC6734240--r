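# nucquant

Single-cell volumetric quantification of nuclear fluorescence in 3-D
confocal stacks — as a fully simulated, testable R pipeline.

## The problem

Many nuclear factors are regulated at the level of *concentration*: a cell
type holds its intranuclear concentration `c` (a.u./µm³) fixed, so the
total amount per nucleus scales with nuclear volume, `T = c·V`. Testing
that claim from microscopy requires an absolute per-nucleus measurement
chain: restore the 3-D stack (deconvolution), isolate each complete
nucleus (segmentation with truncation filtering), and integrate its signal
and volume. `nucquant` implements that chain together with a ground-truth
simulator, so every stage is validated against known truth — no raw image
downloads required. Intended users are microscopists and computational
biologists who quantify per-cell totals/concentrations from confocal
z-stacks, and anyone who needs a reproducible test bed for such pipelines.

The statistics stage provides the field's standard readouts:

* **Constant-concentration fit**: through-origin regression of total on
  volume, `ĉ = Σ T·V / Σ V²`, with bootstrap CI and a
  concentration-vs-volume Spearman diagnostic (≈0 under constancy);
* **Concentration ratios** between cell populations, with bootstrap CIs;
* **DNA-content (ploidy) peak calling** on integrated DNA-stain totals —
  the pipeline's accuracy control: a cycling population must show its G2
  peak at exactly twice the G1 peak;
* **Spearman correlations** between per-nucleus channel totals, with
  exact small-sample permutation p-values;
* **Gel densitometry** by the rectangle-volume method with local
  background subtraction.

The voxel-level core (simulator, separable-kernel Richardson–Lucy
deconvolution with depth bricks, 3-D labelling) is implemented in
R + Rcpp.

## Worked example

Simulate a single cell population with one shared concentration
(3 a.u./µm³, volumes spanning 250–520 µm³), push it through the full
pipeline, and fit the constant-concentration model:

```r
library(nucquant)

cfg <- run_config(preset = "constant_concentration",
                  n_per_type = c(cellA = 12), seed = 11,
                  sampling = c(0.2, 0.2, 0.4))
b <- run_pipeline(cfg)
b$stats$concentration_fit_yfp
#> <concentration_fit> n = 12 nuclei
#>   concentration (through-origin slope): 3.072 a.u./um^3  [3.07, 3.075] 95% CI
#>   through-origin R^2: 1.0000
#>   concentration-vs-volume Spearman rho: -0.490  [-0.957, 0.133]
#>   free-intercept diagnostic: intercept 3.869, slope 3.062
```

The recovered slope is the population concentration (3.07 vs the injected
3.0, i.e. within ~2.5% after rendering, noise, deconvolution and
segmentation); the through-origin `R²` of 1.0000 is the proportionality
the model asserts; the Spearman CI covering 0 says concentration does not
drift with nuclear volume — the constancy signature. `b$comparison` holds
the per-nucleus truth-vs-estimate table, `b$measurements` the measurement
table (label, channel, total a.u., volume µm³, concentration, centroid),
and `plot(b$stats$concentration_fit_yfp)` draws the total-vs-volume cloud
with the fitted radial line.

Other presets: `"cortex"` (two cell types at a 5:1 concentration
contrast), `"cycling_dapi"` (DNA-doubling control), and
`"correlated_channels"` (two-channel Spearman contrast). A thin CLI over
the same functions is in `inst/cli/nucquant.R`
(`simulate | deconvolve | quantify | run` verbs).

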