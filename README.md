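# cortiquant

Quantification of plasma-membrane association in single transversal confocal
sections of budding yeast.

## The problem

In post-diauxic yeast, proteins such as the exoribonuclease Xrn1 are
sequestered at eisosomes — discrete cortical scaffolds on the plasma
membrane that appear as bright punctae along the cell outline in a
mid-plane (transversal) confocal section. Whether, and how strongly, a
GFP-tagged reporter binds the membrane is measured per cell as the
**PM/cytosol ratio**

```
R = mean I(membrane band) / mean I(cell interior)
```

where the membrane band is the set of pixels within a half-width *h*
(default 0.25 µm) of the segmentation-mask boundary on both sides of it
(the mask edge stands in for the plasma-membrane mid-line), and the
interior is the mask eroded by the same *h*. `R > 1` indicates cortical
enrichment; `R < 1` arises when the reporter instead accumulates in bright
cytosolic foci. Whether two channels decorate the *same* cortical
structures is assessed on intensity profiles unwrapped along the membrane
contour: Pearson correlation against a circular-permutation null, and
greedy matching of detected punctae within an arc tolerance.

The package provides the full pipeline: label masks (Cellpose-style, or a
built-in threshold/watershed segmenter for synthetic data) → curated
elliptical cell ROIs (edge-cell removal, rule-based dead-cell exclusion) →
compartment measurements and ratios → membrane profiles and colocalization
→ hierarchical statistics (cells averaged within biological replicates;
replicate means tested by Shapiro–Wilk, Levene, one-way ANOVA and Tukey
HSD with significance stars). A synthetic-micrograph generator with
per-cell ground truth (membrane ring, cortical punctae, cytosolic pool and
foci, PSF blur, Poisson + Gaussian noise) makes every stage verifiable.

## Worked example

```r
library(cortiquant)

cfg <- simulation_config(field_shape = c(512L, 512L), n_cells = 5L,
                         membrane_fraction = 0.6, seed = 42L)
sim  <- simulate_field(cfg)
rois <- filter_edge_cells(mask_to_rois(sim$mask), dim(sim$mask))
meas <- quantify_field(sim$micrograph, sim$mask, rois)
meas[, c("cell_label", "mean_membrane", "mean_interior",
         "pm_cytosol_ratio", "area_um2")]
```

```
 cell_label mean_membrane mean_interior pm_cytosol_ratio area_um2
          1         145.1         41.19            3.522    26.92
          2         161.7         48.67            3.322    21.68
          3         165.4         50.03            3.306    20.93
          4         142.5         40.74            3.498    27.52
          5         169.9         53.41            3.181    19.46
```

Five cells carrying 60% of their signal at the membrane give per-cell
ratios near 3.2–3.5 and cross-sectional areas of 19–28 µm², matching the
simulator's blur-aware expected ratios (3.505, 3.320, 3.292, 3.513, 3.171)
to within a fraction of a percent — the residual is shot and read noise,
not pipeline bias.

## Analysis workflow

The numbered drivers under `analysis/` rebuild the complete synthetic
study (three reporter scenarios × 5 biological replicates × 3 fields) and
write their tables under `results/`:

1. `01_simulate_fields.R` — generate fields + ground truth (TIFFs in
   `scratch/fields`, index in `results/field_index.csv`)
2. `02_quantify_cells.R` — curate masks and measure 540 cells →
   `results/measurements.csv`
3. `03_membrane_profiles.R` — two-channel contour profiles: colocalized
   punctae give mean r ≈ 0.97 and overlap ≈ 0.98, independent punctae fall
   inside the circular-permutation null → `results/coloc_summary.csv`
4. `04_replicate_stats.R` — replicate aggregation and the test battery;
   the strong-binding scenario averages R ≈ 3.2, the weakened one ≈ 1.6,
   and the cytosolic-foci one ≈ 0.42 (< 1), all Tukey pairs `****` →
   `results/stats_pairwise.csv`

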