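---
title: "Quantifying 3D pseudoislets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D pseudoislets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pseudoislets are in-vitro aggregates of alpha cells, beta-like INS1E cells
and HUVEC endothelial cells (seeded 1:9:5, 1500 cells per microwell) that
mimic a pancreatic islet of Langerhans.  They are imaged as multi-channel
3D fluorescence z-stacks: a nuclear stain marking every cell, cytoplasmic
labels marking the INS1E and alpha populations (HUVECs are unlabelled),
and a collagen-IV channel showing the extracellular matrix.  Three
quantities drive the biology: how many cells of each type are present,
how they distribute between the aggregate's *core* and its peripheral
*mantle*, and how many cells touch the ECM.

Counting cells in such stacks is hard: cells touch, signal decays with
imaging depth, and the background is uneven.  Different commercial and
open-source analysis platforms answer the same question with noticeably
different numbers.  This package re-implements, behind one uniform API,
the four published analysis chains (Fiji, CellProfiler, NIS-Elements GA3,
Imaris) as *presets*, together with a synthetic pseudoislet simulator
whose ground truth is exact, and a benchmark harness that reports each
preset's relative count change

\[ \Delta = 100 \cdot \frac{\text{count} - \text{reference}}{\text{reference}} \]

against that truth.

## The processing chains

Each preset is a `pipeline_config` record; `run_preset()` assembles the
operator chain from whichever parameters are set, so custom chains run
exactly like the published ones.

| stage | fiji | cellprofiler | ga3 | imaris |
|---|---|---|---|---|
| rescale to [0,1] | – | yes | – | – |
| rolling ball | 50 px | – | 27 µm | – |
| z-equalisation | – | – | yes | – |
| median filter | – | 5 voxels | – | – |
| Gaussian background | – | – | – | 60 µm (ECM: 20 µm) |
| LoG filter | – | – | sigma 2 px | – |
| binarisation | global Otsu* | adaptive Otsu | global Otsu | global Otsu |
| nuclei counting | 3D components | 3D components | 3D components | 6 µm spots |
| cell surfaces | components | components | components | smooth 0.6 µm, bg 16 µm, split 8 µm |
| size filter | > 250 voxels | – | > 250 voxels | ≥ 353 µm² max slice area |
| core/mantle | – | – | 60 % / 40 % | 80 % / 20 % |
| ECM contact | – | – | 0 µm | 0 µm |

\* the published Fiji chain sets thresholds by hand per channel and
dataset; an unattended run needs a rule, so the preset defaults to a
global Otsu threshold and `manual_threshold` reproduces a hand-picked
cutoff when desired.

Parameters kept in the units they were published in: the Fiji ball radius
is in pixels, the GA3 ball radius in µm; `rolling_ball_unit` makes the
conversion explicit rather than silent.

## Interpretation choices behind the presets

Several published parameters are ambiguous in isolation; the package
fixes one documented interpretation for each:

* **"Gaussian LaPlace filter (power: 2.0)"** (GA3) — implemented as a
  slice-wise Laplacian-of-Gaussian with sigma 2.0 *pixels*, sign-flipped
  so blobs are positive.  No unit is published; `log_sigma` is
  configurable.
* **"Background subtraction set to X µm"** (Imaris) — high-pass filter:
  subtract a Gaussian blur with sigma `X/2` per axis (physical units),
  clipped at zero, which removes structures larger than the filter width.
* **"Size filter ... below 353 µm²"** — an *area* in a 3D pipeline.
  Implemented as the maximum single-slice cross-sectional area per
  object; the voxel-count filter (`> 250`, strict, as printed for Fiji)
  is kept as the alternative path.  Note that 353 µm² exceeds the
  cross-section of a single 10 µm cell (~79 µm²), so after watershed
  splitting this filter removes individual cells and the Imaris-style
  *cell* counts are small; nucleus counting is unaffected because it uses
  spot detection.  This is faithful to the printed parameters rather than
  to their presumable intent.
* **Spot "quality" threshold** (Imaris) — no numeric value is published
  ("adjusted to count all thresholded areas").  The auto rule keeps every
  local LoG maximum reaching 10 % of the peak response: permissive enough
  to keep attenuated deep nuclei, strict enough to reject ripple maxima.
* **Touching-object splitting of 8 µm** — distance-transform watershed
  whose seeds are EDT maxima with closer-than-4-µm (one expected object
  *radius*) duplicates suppressed.  Suppression at the full diameter
  would refuse to split two 8 µm objects overlapping by 25 % (centre
  distance 6 µm), which is precisely the case the parameter exists for.
* **GA3 object cleanup** — the published GA3 text thresholds and counts
  without a printed size gate, which on noisy data would count thousands
  of sub-nuclear LoG ripples.  The preset reuses the `> 250` voxel filter
  printed for the Fiji chain (about half a nucleus volume at the
  benchmark geometry); `min_voxels` is configurable.
* **Contact at "maximum distance of 0 µm"** — a child object interacts
  with a parent when their voxel sets overlap *or touch* (26-adjacency);
  operationally, when the minimum voxel-centre distance does not exceed
  one voxel diagonal.  `adjacency = FALSE` switches to strict overlap.

## The core/mantle partition

Both volumetric presets erode the spheroid mask until a target fraction
of its volume remains as core (60 % for GA3, 80 % for Imaris).  Discrete
erosion steps cannot hit a fraction exactly, so the partition works on
the Euclidean distance transform (computed with physical spacing, so
shells have uniform µm thickness despite anisotropic voxels): the core is
the set of the `round(f * N)` deepest mask voxels, with ties at the
cutoff depth broken deterministically in scan order.  The achieved
fraction is therefore exact to one voxel, well inside the declared
±2 % tolerance, and monotone in the requested fraction.  On a solid
sphere of radius `R` the resulting core is the concentric sphere of
radius `f^(1/3) R`, which the tests verify.

The layer-based rule used by manual counting (mantle = centroid within
`n` cell layers of the surface) is provided separately
(`layer_based_regions()`) so volumetric and layer-based references can be
compared on the same objects.

## The simulator

`simulate_pseudoislet()` produces a `channel_stack` plus exact ground
truth.  Its defaults are the study conditions: 1500 cells at 1:9:5,
6 µm nuclei (radius 3 µm) inside 10 µm cells, aggregate radius 70 µm
(the radius at which 1500 such cells pack at ~0.55 density),
`contact_fraction = 0.9` (cells compressed into contact, as after
centrifugation), depth attenuation `exp(-z/40 µm)`, a small anisotropic
Gaussian PSF (0.3 / 0.9 µm), a smooth polynomial background at 10 % of
peak, and Poisson shot noise (150 photons at unit intensity) followed by
Gaussian read noise.

Design choices worth knowing:

* **Placement** uses a face-centred-cubic lattice sized so the aggregate
  sphere holds exactly `n_cells` sites, jittered uniformly within the
  spacing slack and cleaned up by a short repulsive relaxation.  Purely
  random (dart-throwing) placement cannot reach the study's packing
  density, and long relaxations are slow and seed-fragile; a jittered
  lattice is deterministic, respects the minimum-distance invariant by
  construction, and approximates the near-close-packed arrangement of a
  centrifuged aggregate.  The price is residual local order that real
  aggregates lack.
* **HUVECs render in the nuclei channel only**, so the nucleus count
  exceeds the sum of labelled-cell counts, as in the real data.
* **Mantle definition**: a ground-truth cell is mantle when its centre
  lies within `mantle_layers` cell *diameters* of the aggregate surface.
  The manual convention is ambiguous between one and two peripheral
  layers; the default is **1**, because at the default geometry one layer
  puts ~35–40 % of cells in the mantle (between the published 60/40 and
  80/20 volumetric splits), whereas two layers would put ~64 % of cells
  in the mantle, contradicting every published distribution.
  `mantle_layers` stays exposed.
* **ECM fibres** are random polyline tubes (radius 0.8 µm) confined to
  the aggregate; a cell's `ecm_contact` flag is set exactly when its cell
  sphere reaches a fibre voxel (surface distance ≤ 0), the same
  object-based rule the pipelines use.
* **What the simulator does not model**: realistic optics (no
  Gibson–Lanni PSF, no spectral bleed-through), microwell-wall
  autofluorescence, irregular cell and nucleus shapes, chromatin texture,
  or mitotic figures.  Passing the benchmark on synthetic data therefore
  shows that a preset's operator chain recovers counts under controlled
  degradations — not that it would achieve the same accuracy on real
  stacks.

## Benchmark regimes

`regime_config()` fixes the two study conditions used by the tests:

* **easy** — 200 cells, `contact_fraction = 1` (just touching), no
  attenuation, no PSF, no background, no noise.  Every preset is expected
  to recover the nucleus count within ±5 %.
* **hard** — 200 cells compressed to `contact_fraction = 0.75`,
  attenuation length 40 µm, PSF 0.35/1.0 µm, 10 % background, Poisson +
  Gaussian noise; nine seeds at 128 × 128 × 100 voxels and the default
  benchmark geometry of 0.55 µm pixels (a 2×2-binned 11 µm camera pixel
  behind a 40× objective) and 0.7 µm z-steps.

These sizes keep a full 4-preset × 9-dataset benchmark within a desk-
scale compute budget while leaving the hard regime genuinely hard
(touching nuclei after PSF blur, deep-slice signal at ~30 % of peak).

## Numerical conventions

* Arrays are `(y, x, z)`, column-major; physical positions are
  voxel-centre positions in µm; µm thresholds convert to voxels by
  rounding half away from zero per axis.
* Otsu thresholds use a 256-bin histogram between the grid minimum and
  maximum; ties in between-class variance break toward the lower
  threshold; foreground is `>= t`.  Adaptive mode computes one threshold
  per block, clips block thresholds into `[0.7, 1.5]` times the global
  threshold (so empty blocks cannot invent foreground), and interpolates
  trilinearly between block centres.
* The rolling ball is applied per z-slice with a non-flat (ball-topped)
  structuring element; radii above 10 px use the classic
  shrink/roll/enlarge scheme (block-minimum downscale, opening at reduced
  radius, bilinear upscale).  A ball of radius `r` sinks by the sagitta
  `r - sqrt(r^2 - w^2/4)` into a peak of width `w`, so amplitude
  preservation claims hold only for structures much narrower than the
  ball — the regime all four chains operate in.
* Gaussian blurs with voxel sigmas above 8 run on a block-mean pyramid
  (downsample, blur at reduced sigma compensating the block variance,
  linear upsample); this keeps the 60 µm background subtraction tractable
  and is accurate to well under a percent for the smooth fields it is
  used on.
* Distance transforms use the exact squared-Euclidean algorithm with
  per-axis spacing and a large finite sentinel for "unreached".
* `equalize_z` rescales each slice so the median of its above-Otsu
  voxels matches the brightest slice's; slices without separable
  foreground are left unscaled and flagged in the attached report.  The
  operation is idempotent to numerical tolerance.
* Matching of detections to truth is a Hungarian assignment on distances
  within the match radius (default 6 µm, one nucleus diameter): it first
  maximises the number of matches, then minimises total distance.

## Worked example

```{r example}
library(pseudoislet3d)

geom <- benchmark_geometry()              # 0.55 um pixels, 0.7 um z-step
ds <- simulate_pseudoislet(regime_config("hard", seed = 1), geom,
                           dim3 = c(128, 128, 100))
res <- run_preset(ds$stack, preset("ga3"))
res$counts
relative_change(res$counts[["nuclei"]], nrow(ds$truth))
res$partition$achieved_core_fraction

report <- benchmark_report(list(d1 = ds), c("fiji", "imaris"))
attr(report, "summary")
```

## Known limitations

* Presets reproduce published *parameters*, not the internals of the
  commercial engines; where the original is interactive (Fiji and Imaris
  manual thresholds, Imaris spot quality) an automatic rule stands in and
  is documented above.
* The Imaris-style 353 µm² area filter, applied as printed, suppresses
  individual split cells; cell-count comparisons for that preset measure
  the printed pipeline, not a tuned one.
* TIFF I/O follows the R `tiff` package's conventions: float stacks must
  lie in [0, 1] (16-bit integer stacks round-trip bit-exactly); pixel
  sizes are not embedded, so geometry is always caller-supplied.
* The simulator's cell bodies and nuclei are spheres; segmentation
  difficulty on real, irregular cells will be higher.
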