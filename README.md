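# fretscope

Quantitative analysis of intermolecular FRET biosensor time-lapse imaging.

Conformation-selective biosensors report kinase activity as intermolecular
FRET between a donor-labeled kinase and an acceptor-labeled binder that
recognizes only the open, active state. `fretscope` is for cell biologists
and imaging scientists who need to turn the resulting three-channel confocal
movies (Dex-Dem donor, Dex-Aem raw FRET, Aex-Aem acceptor) into quantitative
statements about where, when and how strongly the kinase is active — plus the
standard wet-lab companion fit, a one-site binding isotherm.

## What it computes

* **FRET index (FRET_T)** — bleed-through-corrected sensitized emission,
  `FRET_T = I_FRET − α_D·I_Donor − α_A·I_Acceptor`, with slopes α_D, α_A
  calibrated from donor-only / acceptor-only samples (defaults 0.55, 0.028),
  optional 2×2 median filter and opt-in 8-bit export; donor-normalized FRET
  and spectral efficiency `Fa/(Fa+Fd)`.
* **Segmentation** — per-frame cell masks (global threshold, erosion, hole
  filling, small-particle removal), centroids, traced boundaries (mask-trace
  or Canny), axis-aligned quadrants, exact Euclidean edge distances.
* **Acceptor photobleaching** — donor recovery `(1 − pre/post)·100`, ΔDonor
  images, and periphery-to-centroid linescan profiles of recovery versus
  distance from the membrane, summarized across bleach doses.
* **Spatio-temporal statistics** — per-quadrant mean FRET_T traces, high-/
  low-FRET quadrant (HFQ/LFQ) summaries, stimulation deltas, dominant pulse
  period via quadratically detrended periodograms, and sector kymographs of
  activity versus distance from the edge.
* **Morphodynamics & motility** — mean fractional area/perimeter change,
  a self-contained signed boundary-velocity map (protrusion positive),
  near-membrane signal at ~1 µm depth, and the binned (width 3 au) cubic fit
  `f = y0 + a·x + b·x² + c·x³` of motility against FRET intensity.
* **Binding** — one-site isotherm `Y = Bmax·X/(K_D + X)` by nonlinear least
  squares with pooled replicates.
* **Synthetic scenes** — a seeded generator (star-convex cell, membrane
  hotspot, 3.5-min activity pulses, realistic noise, bleed-through applied at
  render time) with full ground truth, used by the test suite to validate
  every stage; minimal multi-page TIFF I/O for interchange.

## Worked example

```r
library(fretscope)

# a reference cell: 96x96 px at 0.2 um/px, 50 frames at 2 frames/min,
# membrane hotspot at 45 deg pulsing with a 3.5-min period
cfg <- scene_config(image_shape = c(96, 96), n_frames = 50, cell_radius_px = 30,
                    pulse_period_min = 3.5, hotspot_angle_deg = 45, seed = 1)
res <- run_pipeline(pipeline_config(scene = cfg, seed = 1))

res$compartment_summary$hfq_id                    # "Q2"
res$compartment_summary$max_fret_hfq              # 13.27555
res$dominant_period$period_per_quadrant_min[["Q2"]]  # 3.571429
fit <- fit_one_site(generate_binding_curve(1, 60, c(75, 150, 300, 600, 1250),
                                           noise_sd = 0.1, relative = TRUE,
                                           n_replicates = 3, seed = 1))
fit
# One-site binding fit: Bmax = 1.016 au, Kd = 61.88 nM (R^2 = 0.7656, n = 15)
```

Reading those numbers: the hotspot was planted in the top-right quadrant, and
the pipeline designates exactly that quadrant as the high-FRET quadrant (Q2),
peaking at 13.3 au of corrected sensitized emission. The dominant pulse
period recovered from the detrended periodogram is 3.57 min — the closest
representable frequency-grid value to the true 3.5 min in a 25-min movie.
The binding fit recovers K_D ≈ 62 nM from a noisy 5-concentration, 3-replicate
design generated at 60 nM.

The `analysis/` directory holds the same workflow as numbered narrative
scripts (simulate → calibrate → segment → photobleaching → pulse periods →
morphodynamics/motility → binding fit), each writing tables under `results/`:

```sh
Rscript analysis/01_simulate_scene.R
Rscript analysis/02_calibrate_fret_index.R
# ... through 07_binding_fit.R
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end computation from
scratch — simulating the seeded reference scene, segmenting it, computing the
FRET index, quadrant/period/motility statistics and the binding fit — and
writes the target report as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
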