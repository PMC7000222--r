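---
title: "Quantifying a binder-based FRET biosensor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a binder-based FRET biosensor: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretscope)
```

## The measurement problem

An intermolecular FRET biosensor reports the activity of a kinase: a donor
fluorophore is fused to the kinase, an acceptor-labeled binder recognizes
only the open, active conformation, and energy transfer therefore marks where
and when the kinase is active. Live-cell confocal imaging yields three
channels per time point: donor excitation/donor emission ("donor",
Dex-Dem), donor excitation/acceptor emission (the raw FRET channel,
Dex-Aem), and acceptor excitation/acceptor emission ("acceptor", Aex-Aem).
The raw FRET channel mixes true sensitized emission with two contaminations:
donor emission leaking into the acceptor band and acceptor excited directly
by the donor laser. `fretscope` implements the complete analysis chain from
these stacks to compartmentalization statistics, pulse periods, photobleaching
controls, morphodynamics, motility coupling and binding isotherms.

## FRET index (sensitized emission correction)

The bleed-through-corrected activity map is

FRET_T = I_FRET − α_D · I_Donor − α_A · I_Acceptor,

with slopes calibrated on single-label samples: α_D is the origin-forced
least-squares slope of Dex-Aem against Dex-Dem over cell pixels of a
donor-only sample, α_A the slope against Aex-Aem of an acceptor-only sample
(`estimate_bleedthrough()`); typical values for the cerulean/venus pair used
here are α_D ≈ 0.55 and α_A ≈ 0.028, the package defaults. When multiple
cells are supplied, per-cell slopes are averaged. An optional 2 × 2 median
filter follows the subtraction; because an even kernel has no center we anchor
the block at the top-left pixel (out[r, c] = median of in[r..r+1, c..c+1])
with edge replication, applied per frame immediately after the subtraction.

Numerical choices worth knowing:

* Negative FRET_T pixels (bleed-through over-subtraction) are *retained* in
  the float pipeline; they carry information about calibration error. They
  are clipped only by the opt-in `to_8bit()` export, which models the 8-bit
  conversion used by typical acquisition pipelines (affine min–max or fixed
  window, rounding half-up, constant stacks mapping to zero).
* All analyses run on float stacks by default so generator round-trip tests
  are exact to machine precision.

Donor-normalized FRET (FRET_T divided by donor fluorescence) controls for
sensor expression; pixels with donor below a floor are marked undefined (NA)
rather than zero so they cannot bias means. Spectral FRET efficiency from
cuvette/spectral measurements is Fa/(Fa + Fd).

## Segmentation and geometry

Masks are built per frame from the acceptor channel: global threshold (Otsu
by default; a fixed user threshold is supported, matching the original
user-defined procedure), optional erosion smoothing, hole filling, removal of
components below `min_area_px`, then selection of one component (largest in
frame 1, nearest-centroid linkage afterwards). The default erosion radius is
0: erosion visibly shrinks a clean footprint, and on low-noise data the
threshold alone recovers the cell to Jaccard ≥ 0.99; enable it for noisy
movies. Coordinates are (row, col), 1-based as is natural in R, with pixel
centers at integer coordinates; distances are kept in pixels and converted to
µm only at reporting.

The boundary is an ordered, closed 8-connected loop from Moore-neighbor
tracing; a Canny route (`detect_boundary(..., method = "canny")`) reconciles
the edge map to the outermost closed contour and agrees with the mask trace
to within one pixel on clean data. Perimeter is the chain length with
diagonal steps weighted √2; where an absolute length is needed we apply
Kulpa's 0.948 correction for the systematic overestimation of smooth contours
by 8-chains (ratios of perimeters, as in the morphodynamics metric, cancel
any constant correction).

Quadrants are axis-aligned around the per-frame centroid (Q1 top-left … Q4
bottom-right, image rows increasing downward); pixels exactly on a dividing
line go to the right/bottom side. Image-aligned (not cell-aligned) axes were
chosen as the simpler, figure-consistent reading. The Euclidean distance
transform (`edge_distance()`) is exact (Felzenszwalb–Huttenlocher), verified
against brute force.

## Acceptor photobleaching

Destroying a fraction *b* of the acceptor removes the same fraction of energy
transfer. Writing E for the FRET fraction, the noise-free render model gives
pre-bleach donor D(1 − E) and post-bleach donor D(1 − E(1 − b)), so the donor
recovery (1 − pre/post)·100 has the closed form 100·bE/(1 − E + bE) — equal
to 100·E at full bleach. This identity is the oracle for the linescan stage.

The radial recovery profile samples, for every boundary pixel, the straight
segment to the centroid at unit steps (bilinear interpolation by default,
nearest-pixel optional), pools samples into distance-from-periphery bins
(default width 1 px, exposed as a parameter; the source procedure does not
state one) and computes recovery from the *bin-mean* pre and post intensities
— a ratio of means, more robust at low counts than a mean of per-pixel
ratios, which the source description leaves ambiguous. The distance
coordinate is arc length along the sampled line from its boundary endpoint,
matching the linescan description; the Euclidean edge-distance map is
available separately. Dose labels ("2X", "5X", "10X") are stored verbatim and
never interpreted as power.

One subtlety the tests respect: bins near the centroid pool many line samples
but few *distinct* pixels (all lines converge), so per-seed shot noise does
not average out there. The flatness invariant for uniform pairs is therefore
asserted on the 20-seed mean profile over the outer bins, where each bin
averages tens of independent pixels.

## Quadrant traces, HFQ/LFQ, and stimulation deltas

Quadrant means are exact arithmetic means of FRET_T over mask∩quadrant pixels
(an empty quadrant yields NA, not 0). The high-FRET quadrant (HFQ) and its
Max-FRET_T are located at the global maximum of the 4 × T table; the low
quadrant (LFQ) value is read at the same time point. Ties break to the
earliest time, then the lowest quadrant index — an exhaustive-search oracle
checks this on random tables. Stimulation deltas fix the HFQ/LFQ designation
from the pre-stimulation period and compare per-quadrant maxima before and
after, reporting whether ΔHFQ exceeds ΔLFQ.

## Pulse periods

Traces are detrended by a least-squares quadratic (slow drifts in expression
or focus masquerade as low-frequency power), then a one-sided periodogram is
computed with a rectangular window and no padding; the dominant frequency is
the argmax excluding the zero bin, ties going to the lowest frequency, and
the period is its reciprocal. Uniform sampling is required; traces with
missing frames are rejected rather than resampled. On-grid sinusoids are
recovered exactly; for off-grid periods the resolution is one frequency bin
(1/(T·Δt)); a 3.5-min pulse train in a 25-min movie lands on the 3.57-min
grid point. Periods are estimated per quadrant and averaged per cell where
all quadrants carry signal; in hotspot-only scenes the non-hotspot quadrants
are noise-dominated and only the hotspot quadrant's period is meaningful.

## Sector kymograph

A 40-pixel arc (the conventional arc length; configurable) is anchored on the
membrane either explicitly or at the boundary position with maximal
near-membrane FRET_T (per-boundary-pixel mean over the first 5 ray samples,
circularly smoothed over an arc-length window — the source does not state its
search window, so it is exposed as a parameter). The sector is the union of
straight segments from the arc pixels to the centroid; intensities are pooled
per frame into distance-from-edge bins along those rays, the same distance
convention as the linescan. Geometry is fixed on a reference frame (default
frame 1), matching the construct-once description.

## Morphodynamics and motility

Mean fractional area change is Σ|A_{i+1} − A_i| / A_1 / (n − 1), and the
perimeter analog likewise; both are normalized to frame 1, so reversing the
frame order rescales the metric by exactly A_1/A_n — an algebraic identity
the tests assert. On rasterized disks the metric is discretization-limited:
at radius ~10 px the lattice fluctuation of pixel-count areas is a few
percent of the frame-to-frame change (worst on lattice-aligned centers), which
is why the analytic disk check uses a generic center.

Boundary velocity replaces an external active-contour tracker with a
documented, self-contained definition (no numeric equivalence to any tracker
is claimed): each frame's boundary is resampled to arc-length-uniform points
on a smoothed dense polyline (sub-pixel; identical masks give exactly zero
velocity), and the signed velocity of a point is its distance to the next
frame's polyline, positive inside the next mask (protrusion), negative
outside (retraction), scaled to µm/min. Motility is the modulus. Topology
changes are out of scope (single-component masks are enforced upstream).

Near-membrane signal is the mean FRET_T along each boundary ray down to 1 µm
(5 px at 0.2 µm/px; depths below one pixel are rejected). The motility–FRET
correlation pairs the two grids one-to-one, bins signal into left-closed
width-3 bins aligned to multiples of 3 (the printed bins share endpoints, so
a closure rule is required), averages motility per bin, and fits
f = y0 + a·x + b·x² + c·x³ to bin means versus bin centers (raw-sample fits
are a documented option). R² of a zero-variance response is defined as 0;
fewer than 4 nonempty bins is an error. Spearman's ρ across bins summarizes
the monotone trend.

## Binding isotherms

`fit_one_site()` fits Y = Bmax·X/(K_D + X) by nonlinear least squares
(Gauss–Newton), initialized at Bmax₀ = max(Y), K_D₀ = median(X). Replicates
are pooled into one residual vector by default, matching the convention of
fitting several independent experiments jointly; per-replicate fits are
optional. Both parameters are free (the source is silent on fixing Bmax).
The default convergence test is the relative-offset criterion, which is
scale-invariant and hence preserves exact equivariance (scaling Y scales
B̂max and leaves K̂_D unchanged); it is undefined at zero residuals, so
noiseless data trigger one retry with a scale offset. At the experimental
design — five concentrations from 75 to 1250 nM, three replicates, 10%
relative noise — the median relative K_D error is below 15%; a single
replicate at this design does not constrain K_D that tightly (~20%), which is
why the generator's default emulates the replicated experiment.

## The synthetic scene generator

The generator states a world and the tests measure the pipeline against it:

* **Geometry**: a star-convex radial footprint r(θ, t) = r₀(1 + Σ aₖ
  sin(kθ + φₖ)) plus per-frame random low-order harmonic jitter
  (`boundary_motility_amp_px`, RMS pixels). Star-convexity guarantees that
  periphery-to-centroid lines stay inside the cell, the geometric assumption
  behind the linescan and sector analyses.
* **Activity**: E(x, t) = baseline + hotspot(x)·(level + amplitude·pulse(t))
  + quadratic drift, where the hotspot is a raised-cosine angular window
  hard-limited to its stated width and to a radial depth from the membrane.
  E must stay in [0, 1); configurations that can reach 1 are rejected.
* **Pulses**: raised-cosine pulse trains (period 3.5 min, duty 0.5) by
  default — deliberately non-sinusoidal so the periodogram test is
  non-trivial; a pure sinusoid is available for on-grid exactness tests.
* **Rendering**: donor = D(1 − E), sensitized = D·E, acceptor = A; the
  measured FRET channel adds α_D·donor + α_A·acceptor. This makes the
  bleed-through correction an exact inverse on noise-free scenes.
* **Noise**: Gaussian with variance gain·signal (a Poisson surrogate
  appropriate for photon-counting detectors) plus constant read noise,
  applied last and clipped at zero. No acquisition noise magnitudes are
  published for the source system; the defaults (expression ≈ 100 photon-scale
  units, unit gain, read SD 2) were chosen once as plausible for
  photon-counting confocal detectors and are not tuned.
* **Coupling**: `motility_coupling` scales boundary jitter by (1 + κ ·
  hotspot profile); κ < 0 suppresses motility where activity is high,
  emulating the observed anticorrelation.
* **Determinism**: all randomness flows through one seed; identical seeds
  give bit-identical stacks.

What the generator does *not* emulate: excited-state photophysics, spectral
crosstalk beyond the two linear terms, acceptor maturation/stoichiometry
gradients, focus drift, or multi-cell fields. A green test therefore
establishes the correctness of the computations on a faithful abstraction of
the acquisition — not the biology of any particular cell line.

## Known limitations

* The acceptor-photobleaching stage models bleaching as instantaneous and
  purely acceptor-specific; incidental donor bleaching is not corrected.
* The boundary-velocity definition is nearest-distance based; it does not
  track material points, so tangential membrane flow is invisible to it.
* Periodogram resolution is one frequency bin; short movies quantize the
  reported period (3.57 min is the closest representable value to 3.5 min in
  a 25-min movie).
* The TIFF codec is a minimal baseline reader/writer (uncompressed grayscale,
  uint8/uint16/float32) sufficient for the pipeline's own round trips, not a
  general TIFF implementation.
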