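# regenliver

Tools for the computational side of a biliary-driven liver-regeneration
study: after severe hepatocyte ablation in adult zebrafish, biliary
epithelial cells (BECs) dedifferentiate and rebuild the hepatocyte
compartment. Tracking that conversion required three bespoke analyses that
this package provides as tested, reusable functions:

1. **Droplet preprocessing** — slope-based cell calling on the
   barcode-rank curve plus per-gene ambient-RNA subtraction. With barcodes
   ranked by total UMIs, the cumulative-read-fraction slope at rank *i* is
   that barcode's share of the total; barcodes at or above the average
   slope (exactly 1/N) are cells, the rest background. Ambient background
   per gene is the nearest-rank 95th-percentile count across background
   barcodes, subtracted everywhere with a zero floor.
2. **Cell-state expression analytics** — log-normalization
   (`ln(1 + c/T·10⁴)`), dot-plot statistics, one-vs-rest Wilcoxon marker
   detection (positive-only, Bonferroni-corrected, p_adj < 0.05),
   ≥3-marker cluster identification, merging of indistinct clusters,
   cell-state construction (`timepoint.cell_type`, e.g. `2dpa.BEC`), and
   row min-max scaled average-expression heatmaps, including cross-species
   ortholog heatmaps.
3. **Image quantification** — Otsu-based cellular (GFP ∪ mCherry) and
   nuclear (DAPI) masks, an exactly-one-nucleus filter, per-cell
   morphometry (area; eccentricity `sqrt(1 − λmin/λmax)` of the
   moment-matched ellipse), reporter-based lineage calls, biliary-derived
   hepatocyte fractions, and %-marker-positive-nuclei time courses with
   rank-sum tests vs mock and mean ± SEM per timepoint.

Synthetic-data generators with analytic ground truth (droplet libraries,
state-structured counts, rendered multi-channel cell images) back every
stage, so the whole pipeline is testable without any download. The
statistical primitives (exact/approximate Wilcoxon rank-sum, Bonferroni,
SEM) are implemented in-package and validated against independent oracles.

## Worked example

```r
library(regenliver)

# -- droplet stage: 50 true cells among 2,000 ambient barcodes ----------
sim <- simulate_droplets(droplet_sim_spec(seed = 1))
pre <- preprocess_droplets(sim$counts)
glance(pre$classification)
#>   n_cells n_background average_slope max_barcodes_used
#> 1      50         2000      0.000488              2050
```

All 50 simulated cells and none of the 2,000 ambient barcodes are called
cells (the average slope 1/2050 separates the two depth regimes), and
`pre$counts` is the background-subtracted, cell-only matrix.

```r
# -- expression stage: markers and a branch heatmap ---------------------
ss <- simulate_state_expression(state_sim_spec(seed = 2))
nm <- log_normalize(ss$counts)
head(find_markers(nm, ss$states$cell_type), 4)
#>   gene     cluster avg_in avg_rest log_fc pct_in pct_out  p_value    p_adj
#> 1 cldn15la BEC       5.69     2.37   2.19  0.937    0.52 6.43e-35 6.56e-33
#> 2 krt18a.1 BEC       5.49     2.12   2.30  0.93     0.47 1.68e-34 1.71e-32
#> 3 anxa4    BEC       5.43     2.55   2.04  0.92     0.55 3.09e-28 3.15e-26
#> 4 sox9b    BEC       5.32     2.62   2.06  0.903    0.57 3.25e-27 3.32e-25

state_heatmap(nm, ss$states, genes = c("anxa4", "fabp10a", "pcna"),
              column_order = c("mock.BEC", "0dpa.BEC", "1dpa.BEC",
                               "2dpa.BEC", "3dpa.HC", "7dpa.HC"))
#>         mock.BEC 0dpa.BEC 1dpa.BEC 2dpa.BEC 3dpa.HC 7dpa.HC
#> anxa4       1.00     0.87     0.71     0.50    0.20    0.00
#> fabp10a     0.11     0.00     0.00     0.13    0.90    1.00
#> pcna        0.00     0.20     0.80     1.00    0.84    0.19
```

The top markers recovered for the BEC cluster are the biliary panel genes,
and the scaled heatmap (each row stretched to [0, 1]) reads as the
regeneration narrative: biliary identity (*anxa4*) decays along the
hepatocyte branch, the hepatocyte program (*fabp10a*) switches on at
3 dpa, and proliferation (*pcna*) peaks at 2 dpa. `autoplot()` renders
any of these results with ggplot2.

```r
# -- imaging stage: segment and measure a rendered field ----------------
field <- simulate_image(random_image_spec(n_cells = 6, seed = 3))
quantify_field(field$image)[, c("cell", "area", "eccentricity",
                                "nucleus_count", "intensity_gfp")]
#>    cell  area eccentricity nucleus_count intensity_gfp
#> 1     1   546        0.241             1          178.
#> 2     2   375        0.499             1          140.
#> ...
```

Each rendered cell is recovered with its pixel area, moment-based
eccentricity, nucleus count, and channel intensities;
`classify_lineage()` and `biliary_derived_fraction()` then turn reporter
intensities into lineage calls, and `positive_nuclei_fraction()` +
`timecourse_test()` produce the per-timepoint mean ± SEM and
Bonferroni-adjusted rank-sum p-values vs mock.

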