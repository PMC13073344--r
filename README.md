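# mfgmorph

Image-based morphometric analysis (IBMA) of milk fat globules (MFGs) in
bright-field micrographs, for dairy and human-milk researchers who need more
than a bulk size distribution: per-particle shape, explicit
individual-vs-agglomerate classification, and a statistical ledger for
comparing imaging against laser diffraction (LD) on the same samples.

Milk fat globules are 1–15 µm triacylglycerol droplets; part of them occur as
**agglomerates** — fused clusters that project as a single low-circularity
silhouette and that bulk methods such as LD cannot resolve. `mfgmorph`
implements the complete chain:

1. **Synthetic scenes** (`generate_scene()`): dark near-circular globules with
   lognormal diameters plus chain-model agglomerates of overlapping disks,
   rendered with exact per-particle ground truth, so every downstream stage is
   testable without any raw data.
2. **Segmentation** (`binarize()`, `label_particles()`): a pixel is foreground
   iff its intensity is below `calibration_intensity × 255 ×
   (1 − intensity_tolerance)` (163.2 with the SOP defaults); connected
   components at configurable 4/8-connectivity, 25-px detection floor, border
   exclusion.
3. **Morphometry** (`measure_particles()`): circle-equivalent (CE) diameter
   `2·sqrt(A/π)`, HS circularity `4πA/P²`, convexity, solidity, elongation,
   Feret length/width, intensity statistics. The perimeter comes from a
   corner-corrected chain code (diagonals weighted √2, corner constant
   ≈ 0.12077 derived so digital disks converge to `πd`, plus a half-pixel
   `π·s` margin term); naive edge counting would inflate perimeters ~27% and
   misclassify circular globules against the 0.920 threshold.
4. **QC + classification** (`qc_filter()`, `classify_particles()`): exclude
   particles with convexity < 0.750, solidity < 0.700, area < 100 px, or
   intensity SD < 10; then *individual* = circularity ≥ 0.920 and CE
   diameter < 25 µm, *agglomerate* = circularity < 0.920 and
   solidity < 0.970, remainder *unclassified* but counted in the total.
5. **Size metrics** (`number_metrics()`, `volume_metrics()`): D[1,0], Pn10/50/90
   and D[4,3] = Σd⁴/Σd³, Pv10/50/90 on raw diameter lists under one shared
   cumulative-fraction percentile rule (which guarantees Pv ≥ Pn).
6. **Method agreement** (`method_agreement()`, `compare_methods()`): Pearson r,
   Lin's concordance correlation coefficient
   `r_c = 2s_xy / (s_x² + s_y² + (x̄ − ȳ)²)` (1/n moments), paired t, Bland–
   Altman bias with 95% limits of agreement `d̄ ± 1.96·SD`, proportional-bias
   regression of the difference on the paired mean, and BCa bootstrap
   confidence intervals (3000 resamples; jackknife acceleration;
   order-statistic endpoints).
7. **Study tables** (`load_study_tables()`, `reproduce_study_summaries()`): the
   per-sample covariates, class counts, and size/shape metrics of a 12-donor
   human-milk study, checksum-pinned, with a report that recomputes every
   printed summary statistic.

## Worked example

Simulate a noisy scene, run the pipeline, and compare two methods:

```r
library(mfgmorph)

spec <- scene_spec(640, 640, n_individuals = 40, n_agglomerates = 12,
                   pixel_size_um = 0.2, noise_sd = 8, seed = 42)
sc <- generate_scene(spec)
res <- analyze_images(sc$image, pixel_size = 0.2, sample_ids = "demo")
res$summary[, c("class", "n", "d10", "pn50", "pn90", "d43", "pv50")]
#>         class  n   d10  pn50  pn90   d43  pv50
#> 1       total 51 5.286 4.715 7.638 7.307 7.191
#> 2  individual 39 4.564 4.332 6.232 5.547 5.300
#> 3 agglomerate 12 7.630 7.306 9.416 8.614 8.965
```

Of the 52 rendered particles, 51 survive QC (one small globule falls below
the 100-px area floor) and every survivor is classified to its ground-truth
class: agglomerates are larger (D[1,0] 7.6 vs 4.6 µm) and carry more of the
volume-weighted tail, exactly the pattern that motivates separating them.

```r
pm <- generate_paired(paired_sim_spec(12, slope = 1.25, intercept = -0.5,
                                      noise_sd = 0.8, seed = 7))
method_agreement(pm$x, pm$y, labels = c("LD", "IBMA"), seed = 7)
#> Method agreement (LD vs IBMA), n = 12
#>   Pearson r      0.994  [0.949, 0.997] BCa 95%
#>   CCC (r_c)      0.910
#>   Paired t       t = -4.934, p = 0.0004465
#>   Mean bias      -2.576 (SD 1.808)
#>   95% LoA        [-6.12, 0.9685]
#>   Prop. bias B   -0.223  [-0.314, -0.140]  *CI excludes 0*
```

The simulated method B overreads by 25% proportionally: correlation is
nearly perfect, yet concordance is attenuated (0.91), the paired t flags a
systematic bias, and the proportional-bias slope's BCa interval excludes
zero — the distinction between *association* and *agreement* the ledger is
built to expose.

`reproduce_study_summaries()` recomputes the packaged study's printed
summary rows (mean agglomerate percentage 15.25%, D[1,0] of 4.91/4.36/8.00 µm
for total/individual/agglomerates, storage-duration correlations −0.481 and
−0.631, …) and flags the four printed values that cannot be reconciled with
the per-sample tables.

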