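# pseudoislet3d

Quantification of multicellular **pseudoislets** — in-vitro aggregates of
alpha cells, beta-like INS1E cells and HUVEC endothelial cells (seeded
1:9:5, 1500 cells per microwell) that mimic a pancreatic islet of
Langerhans — in multi-channel 3D fluorescence z-stacks.

Image-analysis platforms disagree substantially when counting cells in
dense 3D aggregates: cells touch, signal decays with depth, and
background is uneven.  This package re-implements four published analysis
chains (Fiji, CellProfiler, NIS-Elements GA3, Imaris) as **presets**
behind one API, adds a **synthetic pseudoislet simulator** with exact
ground truth, and provides a **benchmark harness** that scores every
preset by the relative count change

    Δ = 100 × (count − reference) / reference

against that truth — the over/underestimation metric used in software
comparisons, with the simulator's exact truth standing in for manual
reference counts.

What the package computes, per channel and preset:

* **counts** of nuclei (all cells), INS1E and alpha cells — via 3D
  connected components, LoG spot detection, or surface detection with
  distance-transform watershed splitting, depending on the preset;
* **core/mantle localisation** — an erosion-based volumetric partition of
  the spheroid mask to a target core-volume fraction (60 % for the
  GA3-style chain, 80 % for the Imaris-style chain), plus the layer-based
  rule used by manual counting;
* **cell–ECM contacts** — object-based co-localization against the
  collagen-IV channel at a maximum surface distance of 0 µm
  (overlap-or-touching).

## Worked example

Simulate one "hard-regime" pseudoislet (200 touching cells, depth
attenuation, PSF blur, background, shot and read noise) and run the
GA3-style preset:

```r
library(pseudoislet3d)

geom <- benchmark_geometry()   # 0.55 um pixels, 0.7 um z-step
ds   <- simulate_pseudoislet(regime_config("hard", seed = 1), geom,
                             dim3 = c(128, 128, 100))
res  <- run_preset(ds$stack, preset("ga3"))

res$counts
#> nuclei  insle  alpha
#>    200      1     14

relative_change(res$counts[["nuclei"]], nrow(ds$truth))
#> [1] 0
res$partition$achieved_core_fraction
#> [1] 0.6
```

Reading the output: the chain recovers all 200 nuclei exactly (relative
change 0 %), and the erosion partition hits the requested 60 % core
volume.  The INS1E count collapses to 1 because the 120 touching
cytoplasm shells merge into a single connected object — the
cytoplasm-channel underestimation these software comparisons are about —
while the sparser alpha cells (13 seeded) stay countable at 14.  Every
stage logs its resolved parameters (`res$log`).

The full four-preset comparison over nine simulated datasets:

```r
datasets <- lapply(1:9, function(s)
  simulate_pseudoislet(regime_config("hard", seed = s), geom,
                       dim3 = c(128, 128, 100)))
report <- benchmark_report(datasets)
attr(report, "summary")   # mean relative change per preset and channel
```

A thin CLI wraps the same functions:

```sh
pseudoislet3d simulate  --seed 0 --geometry 0.55,0.7 --out sim/
pseudoislet3d run       --preset imaris --in sim/stack.tif --geometry 0.55,0.7 --out out/
pseudoislet3d benchmark --n-datasets 9 --seed 0 --regime hard --out bench/
```

See `vignettes/pseudoislet-quantification.Rmd` for the model, the
interpretation choices behind each preset, simulator realism and
limitations.

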