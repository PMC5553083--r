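# photondecon

Simulation and restoration of **very weak (photon-counting) confocal
fluorescence Z-stacks** in R — for microscopists and image-analysis
developers who need to test, quantitatively, how image restoration
treats signals of only a handful of photons per object.

At these intensities a pixel rarely records more than 2 photons, and
maximum-likelihood deconvolution can erase real structures. A small
**Gaussian blur prefilter** (sigma 0.75–1.00 px) applied to the optical
sections before deconvolution spreads each photon over a few pixels and
lets weak objects survive restoration with their integrated intensities
essentially unchanged. This package provides everything needed to study
that effect end to end:

* a **Born & Wolf PSF** generator and the effective confocal PSF
  (excitation x emission product), quadrature-converged:

  h(r, z) = | ∫₀¹ J₀(k·NA·r·ρ) · exp(−i·k·z·ρ²·NA²/(2n)) · ρ dρ |²,  k = 2π/λ

* a **simulator** of faint point-source arrays: zero-padded FFT
  convolution, peak normalization to 1 expected photon, optional
  0.01 photons/voxel background, per-voxel Poisson sampling, and the
  8-bit photon-count encoding (code 255 = 4 photons);
* the **prefilter**: separable truncated Gaussian, reflect boundaries,
  flux-preserving, 2D (per slice) or 3D;
* **Richardson–Lucy** maximum-likelihood deconvolution with an additive
  background inside the Poisson forward model,
  x ← x ⊙ H̃( d ⊘ (H x + b) ), FFTW-backed, fixed 40 iterations,
  monotone log-likelihood trace, returned as a classed fit object with
  `print`/`summary`/`plot`/`logLik`/`fitted`/`residuals` methods;
* **quantification**: average projections, 20x20 ROI integrated
  densities, and preserved-object counting against background ROIs at
  the object-lattice midpoints (a 5-sigma operational criterion);
* a **pipeline driver** comparing the `raw`, `decon` and `blur_decon`
  arms with full seed/checksum provenance, plus a thin CLI
  (`inst/scripts/photondecon`) with `simulate`, `blur`, `deconvolve`,
  `project`, `quantify` and `experiment` subcommands.

See the vignette (`vignettes/photon-counting-deconvolution.Rmd`) for
the model, the numerical choices, and known limitations.

## Worked example

Simulate the reference conditions — an 8x8 array of point sources, one
expected photon at the brightest voxel, Poisson noise, 8-bit encoding —
then compare no processing against blur-then-deconvolve:

```r
library(photondecon)

cfg <- experiment_config(
  sim = sim_config(seed = 1),      # 200 x 200 x 40 grid, 80 x 80 x 250 nm voxels
  deconv_background = 0,
  pipelines = c("raw", "blur_decon")
)
res <- run_experiment(cfg)
print(res)
#> Experiment (master seed 1): arms raw, blur_decon
#>   raw         50/64 objects preserved, median density 0.2008
#>   blur_decon  60/64 objects preserved, median density 0.1976

compare_reports(res$arms$raw$report, res$arms$blur_decon$report)
#> Report comparison over 64 objects: median density ratio 0.9875
#>   preserved 50 vs 60 (delta +10)

print(res$arms$blur_decon$fit)
#> Richardson-Lucy ML deconvolution
#>   40 iterations on a 200 x 200 x 40 stack, background 0 photons/voxel (manual)
#>   estimate total 501.176 photons, flux scale 1
#>   final log-likelihood -1614.7
```

Reading the numbers: the prefilter arm preserves 10 more of the 64
simulated objects than the raw projection at matched conditions, while
the per-object integrated densities stay within ~1% of the raw values
(median ratio 0.9875) — restoration does not inflate or deplete object
intensities. With ~7.7 expected photons per object the faintest
realizations sit at the 5-sigma detection floor, so neither arm reaches
64/64 (the vignette discusses why absolute counts are photon-limited
while the arm-to-arm comparison is stable).

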