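# adipo3d

Three-dimensional adipocyte morphometry for cleared adipose tissue.

## What this solves, and for whom

Adipocyte size distributions are a primary readout of adipose tissue
remodelling, but adipocytes are large, fragile cells whose true geometry is
only visible in intact, optically cleared tissue imaged in 3D. Two-channel
confocal stacks — an extracellular-matrix (ECM) stain outlining cell walls
and a lipophilic dye filling the interior — make individual cells
segmentable; what remains is the quantification chain. `adipo3d` implements
that chain for imaging labs and quantitative biologists:

- **per-cell 3D morphometry** from any instance segmentation (including
  externally produced masks, e.g. Cellpose output): volume,
  surface area (multi-directional Crofton estimator), equivalent spherical
  diameter, sphericity, centroid, border contact;
- **mask quality control**: discard masks touching the stack border, masks
  under 5000 voxels (≈ 25 µm equivalent diameter at 1.15 µm spacing) and
  masks with sphericity under 0.35, with per-rule removal accounting;
- **a classical seeded-watershed segmenter** for self-contained runs on
  two-channel (in situ) or single-channel (ex situ) stacks;
- **depot statistics**: kernel density estimates (Silverman bandwidth, as in
  `geom_density()`), a permutation two-sample Kolmogorov–Smirnov test with
  the Phipson–Smyth p-value estimator, and a linear model for tissue, sex
  and body-weight effects on per-sample means;
- **a synthetic tissue generator** (lognormal diameter draws; ball-clipped
  Laguerre packing with carved ECM walls for angular in situ cells; sparse
  digitized spheres for extracted cells; exponential depth attenuation)
  that makes every stage testable against known ground truth.

The morphometry core, for a cell of volume $V$ and surface area $A$:

$$d_{eq} = \left(\frac{6V}{\pi}\right)^{1/3}, \qquad
\psi = \frac{(36\pi V^2)^{1/3}}{A}$$

and the permutation test p-value, with $b$ of $m$ permuted statistics at or
above the observed $D$:

$$p = \frac{b + 1}{m + 1} \ \ge \frac{1}{m+1} > 0.$$

## Worked example

Simulate a small two-depot tissue pair, segment, measure, filter and
compare (≈ 1–2 minutes):

```r
library(adipo3d)
res <- run_pipeline(list(
  out_dir = "results/demo_readme", seed = 7,
  simulate = list(n_subjects = 1, tissues = c("VAT", "SCAT"),
                  n_cells_target = 60),
  compare  = list(m = 10000)))
```

The run logs each stage; with seed 7 it prints:

```
[simulate] 2 samples -> results/demo_readme/sim
[segment] S01_VAT: 85 cells (thresholds: lipid=0.475, ecm=0.29)
[segment] S01_SCAT: 80 cells (thresholds: lipid=0.475, ecm=0.297)
[measure] S01_VAT: 85 cells
[measure] S01_SCAT: 80 cells
[qc] S01_SCAT: 80 in, 60 retained (border 18, volume 2, sphericity 0)
[qc] S01_VAT: 85 in, 61 retained (border 22, volume 2, sphericity 0)
[compare] equivalent_diameter by tissue: D = 0.4197, p = 0.0001
```

Reading the output: the watershed finds the 60 true cells of each sample
plus a couple of dozen spurious labels carved out of the empty space
around the tissue; the border and minimum-volume filters remove almost
exactly those (one VAT oversegmentation fragment also survives), so 60–61
cells per depot remain after QC. The permutation KS test then separates
the two depot size distributions (visceral-like, mean 81.32 µm, versus
subcutaneous-like, mean 63.88 µm) at the smallest p-value 10,000
permutations can produce, $1/10001 \approx 10^{-4}$. Per-cell tables are in
`results/demo_readme/qc/`, the density curves in `densities.csv`, the KS
result in `ks_result.json`.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate_cohort.R` … `05_clearing_depth.R`) writing under
`results/demo/`.

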