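---
title: "Methods: quantifying plasma-membrane association in yeast confocal sections"
author: "cortiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying plasma-membrane association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortiquant)
```

## The measurement model

A transversal (mid-plane) confocal section renders a yeast cell as a
filled, approximately elliptical region whose outline carries the plasma
membrane. Given a label mask whose edges trace the membrane mid-line (a
Cellpose-style segmentation, or this package's built-in segmenter for
synthetic data), each cell is partitioned into three compartments by the
Euclidean distance transform of its binary mask:

* **whole cell** — all mask pixels;
* **membrane band** — pixels within a half-width $h$ of the mask boundary,
  *on both sides* of it, excluding pixels belonging to other cells; a
  background pixel between two nearby cells is owned by the nearer
  boundary, ties going to the lower label;
* **interior** ("cytosol") — mask pixels farther than $h$ inside the
  boundary, i.e. the mask eroded by $h$.

The per-cell membrane-association metric is the PM/cytosol ratio
$R = \bar I_{\mathrm{band}} / \bar I_{\mathrm{interior}}$ of mean
intensities. $R$ is invariant to multiplicative intensity rescaling
(detector gain), while any additive offset pulls it toward 1 — so a
constant-background option is the only background model offered, and
uncorrected offsets bias conservatively. Division contracts: a zero
interior mean with a positive band mean yields a $+\infty$ sentinel; both
zero yields an undefined flag; a cell whose interior is emptied by the
erosion (radius $\le h$) is flagged degenerate and excluded from ratio
statistics with a logged reason.

Two accounting identities hold exactly and are enforced in tests: the
whole-cell pixel count equals interior plus intra-mask band pixels, and
integrated intensity equals mean × count in every compartment.

### Why the interior is eroded

Bright cortical signal spreads over roughly the diffraction limit; an
un-eroded "cytosol" would be contaminated by the membrane ring's tails.
Eroding by the same $h$ that defines the band makes the two compartments
complementary inside the mask. Cytosolic foci are deliberately *not*
masked out of the interior: focal accumulations are part of the cytosolic
pool, which is precisely what drives $R$ below 1 for reporters that have
lost membrane binding.

### Band half-width

$h$ defaults to 0.25 µm (≈3 px at 0.08 µm/px), comparable to the lateral
diffraction limit of a high-NA (1.46) oil objective. The width used by any
given legacy macro set is rarely reported; $h$ is therefore an explicit,
configurable parameter, and a half-open convention (a pixel at distance
exactly $h$ belongs to the band) makes the partition deterministic. Both a
symmetric band (default) and an intra-mask-only band (`band_mode =
"inner"`) are computed, since conventions differ between laboratories.

## Cell ROIs and curation

Labels are converted to ROIs with a moment-equivalent ellipse (semi-axes
$2\sqrt{\lambda_i}$ of the pixel-coordinate covariance eigenvalues, the
standard "fit ellipse" behaviour of Fiji-style workflows; a 1/12 term
accounts for the unit-square pixel footprint). Near-circular cells
($a/b < 1.02$) carry a degenerate-orientation flag because their major-axis
direction — and hence the arc origin of membrane profiles — is arbitrary.

Curation is rule-based so that it is reproducible and auditable:

* cells whose mask pixels touch the field border (margin 1 px, inclusive)
  are flagged as incompletely imaged and removed;
* an exclusion-list file (`field_id,cell_label` per line) replaces
  interactive removal of mis-segmented or dead cells;
* an optional automated rule flags cells whose whole-cell mean intensity
  deviates from the field median by more than $k$ (default 5) scaled MADs —
  dead cells typically image far dimmer or brighter than the population.

Both filters are idempotent and order-independent; every stage logs cell
counts, and the run manifest asserts
`cells_in = retained + edge + excluded + degenerate` per field.

## Membrane profiles and colocalization

For profile analysis the fitted ellipse, not the pixelated mask boundary,
is the sampling contour: it provides smooth normals and a reproducible arc
origin (the major-axis vertex, counter-clockwise). At `n_samples` points
equally spaced in arc length, the profile records the maximum image
intensity along the local normal within $\pm h$ (bilinear interpolation,
0.25 px steps). The radial **max** is the default statistic because
eisosomal punctae are narrower than the band — a radial mean would dilute
their contrast; `stat = "mean"` is available. Profiles are min–max
normalized per channel for display and peak detection; a channel whose
range is negligible relative to its magnitude (relative tolerance
$10^{-9}$, absorbing interpolation round-off on flat images) maps to 0.5
with a constant flag.

Two-channel association uses the Pearson correlation of the *raw*
profiles — min–max scaling is affine, so plotted and tested quantities
agree. Because profile samples are strongly autocorrelated (PSF plus ring
continuity), significance comes from a circular-permutation null: channel
2 is circularly shifted by random offsets (1000 by default), preserving
each channel's autocorrelation while destroying registration. Cortical
punctae are detected as circular local maxima with prominence ≥ 0.2 of the
normalized range, thinned to a minimum arc separation (higher prominence
wins, ties to the lower arc position), and matched across channels
greedily, nearest circular distance first, within 0.3 µm; the overlap
fraction is reported relative to channel-1 peaks (undefined when channel 1
has none).

## Replicate statistics

Cells within one biological replicate are technically correlated, so the
unit of inference is the replicate: cell ratios are averaged per
(condition, replicate) — excluding degenerate cells and infinity/undefined
sentinels, with exclusion counts logged — and the replicate means enter
the tests. Shapiro–Wilk (Royston approximation, enforced $3 \le n \le 50$)
per condition and Levene's test (classic centre = mean; median gives
Brown–Forsythe) act as assumption gates for one-way ANOVA with Tukey HSD
(Tukey–Kramer for unequal group sizes). When a gate fails the battery
still reports the ANOVA together with the gate outcome and a warning,
rather than silently substituting another test — with $n = 5$ replicates
per group the gates are weak, and which fallback (if any) is appropriate
is a judgement the analyst must make. Degenerate inputs are given exact
conventions: zero between-group variation reports $F = 0$, $p = 1$;
identical groups give all Tukey adjusted $p = 1$. Stars use inclusive
thresholds: `****` $p \le 10^{-4}$, `***` $\le 10^{-3}$, `**` $\le 0.01$,
`*` $\le 0.05$, else `ns`.

Note the hierarchical example: replicates with cell ratios $\{1,1\}$ and
$\{3\}$ give a condition mean of 2 (mean of replicate means), not $5/3$.

## The synthetic-field generator

`simulation_config()` / `simulate_field()` emulate the imaging scenarios
the pipeline is meant for, with per-cell ground truth. Defaults model
post-diauxic yeast on a 100×/1.46 NA point-scanning confocal:

| parameter | default | meaning |
|---|---|---|
| `pixel_size` | 0.08 µm | Nyquist-ish sampling at 1.46 NA |
| `cell_semiaxis_range` | 2–3 µm | cells 4–6 µm across |
| `cell_total_intensity` | 3×10⁵ | per-cell signal, arbitrary units |
| `membrane_fraction` | 0.6 | signal fraction in the membrane pool |
| `puncta_per_cell`, `puncta_sigma` | 6, 0.1 µm | discrete eisosomal punctae |
| `puncta_enrichment` | 0.5 | membrane signal concentrated in punctae vs uniform ring |
| `ring_fwhm` | 0.25 µm | diffraction-limited membrane ring profile |
| `n_foci`, `foci_fraction` | 0, 0 | P-body-like cytosolic accumulations |
| `psf_sigma` | 0.1 µm | Gaussian PSF |
| `background_level` | 10 | constant offset |
| `photon_gain`, `read_noise_sd` | 1, 2 | Poisson scale and Gaussian read noise |

Cells are non-overlapping ellipses placed by rejection sampling (bounded
attempts; an over-dense configuration errors out), with an optional count
of deliberately edge-clipped cells for filter testing. Rendering
normalizes each signal component to its exact configured total, so
noise-free integrated intensity is conserved. The membrane ring follows
the *rasterized* mask boundary (signed distance from two distance
transforms), which keeps the simulated ring and the measurement band
geometrically consistent. Punctae sit at uniformly drawn contour arc
positions with a minimum separation of 2×`puncta_sigma` (violating sets
are redrawn); a second channel can share those positions exactly, share
them up to a Gaussian arc jitter, or draw its own. The noise order is
fixed — blur, then Poisson on the blurred flux, then additive Gaussian —
because shot noise physically acts on the blurred photon stream. Final
images are rounded to integer DNs so that written 16-bit TIFFs round-trip
bit-identically.

Two expected ratios are recorded per cell. The **geometric** ratio is
measured on the placed, unblurred, background-free signal using intra-mask
band pixels only: it is the density contrast of the configured partition
and equals exactly 1 for a uniform cell. The **blur-aware** ratio is
measured on the noise-free blurred image *with* background using the full
symmetric-band geometry — it is what an ideal pipeline reading the blurred
image would report, so comparing recovered ratios against it isolates
pipeline error from PSF bias. Recovery tests use the blur-aware value.

What the generator does **not** emulate: 3-D stacks and out-of-plane
light, budding morphology, vacuole exclusion, chromatic aberration,
bleaching, detector nonlinearity, or spatially varying background. Passing
the recovery tests therefore demonstrates correctness of the measurement
geometry and statistics under idealized ellipse-shaped cells — not
robustness to every artefact of real micrographs, where segmentation
quality dominates.

## Built-in segmenter

Real workflows use Cellpose; the built-in segmenter exists so synthetic
studies run self-contained. Fluorescence fields are background-dominated,
which defeats histogram-splitting thresholds, so the foreground threshold
is the field median plus 5 scaled MADs (a MAD of zero — noise-free
renders — degrades to "anything above the median"). Hole filling, a 5-px
disc opening and a distance-transform watershed split touching cells. Each
object's boundary is then refined: radial intensity profiles along 72 rays
locate the membrane-ring ridge, and the two ellipse semi-axes are
re-fitted to the per-ray ridge radii by least squares, so the final mask
edge intersects the ring in its middle — the same convention assumed of
external masks. Cells without a prominent ridge (ratio < 1.3 over the
interior level) instead keep the thresholded region re-cut at the half-max
between background and interior medians, which for a blurred step edge
sits on the true boundary.

## Numerical conventions

* Matrices are row = image y; pixel centers at integer 0-based
  coordinates; ellipse orientation in $[0, \pi)$ from the +x axis.
* Distance-transform values put a boundary-adjacent pixel at distance 1;
  band membership uses $\le$.
* CSV writers emit a fixed column order and 6 significant digits, with
  `inf`/`nan` tokens for the ratio sentinels, so identical runs produce
  byte-identical files.
* All stochastic stages consume an explicit seed; a pipeline run fans its
  single config seed out to per-field seeds through a fixed integer
  recurrence, so one number reproduces the whole run.

## Problem sizes

The shipped study simulates 3 conditions × 5 replicates × 3 fields × 12
cells (540 cells); recovery checks use 5 fields × 20 cells per membrane
fraction (0.2 / 0.5 / 0.8) at default noise; colocalization checks use 20
cells per mode with 1000-shift permutation nulls; null-calibration uses
2000 simulated ANOVAs and 1000 Levene tests. These sizes give stable means
(recovery error well under 1%, binomial SE on rejection rates ≈ 0.5%)
while keeping a full rebuild in the minutes range on a single core.

## Known limitations

* The fitted-ellipse contour under-resolves strongly non-elliptical cells
  (buds, mating projections); profiles there sample inside or outside the
  true membrane and the band partially compensates.
* The MAD dead-cell rule assumes most cells in a field are healthy; fields
  with majority dead cells need the exclusion list.
* Tukey HSD assumes homoscedastic replicate means; the battery reports the
  Levene gate rather than switching to a heteroscedasticity-robust
  procedure.
* The permutation null conditions on each cell's own profile; cross-cell
  pooling of correlations is left to the analyst.
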