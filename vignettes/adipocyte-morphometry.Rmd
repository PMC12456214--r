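---
title: "Quantifying adipocyte size and shape in 3D: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adipocyte size and shape in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Adipose tissue stores lipid in very large, fragile cells whose size
distribution is a primary readout of tissue remodelling. In intact,
optically cleared tissue (in situ), adipocytes are packed against each
other and flattened into angular polyhedra by extracellular-matrix (ECM)
walls; freshly extracted cells (ex situ) relax into near-perfect spheres.
Two-channel confocal stacks -- an ECM stain delineating walls and a
lipophilic dye filling the cell interior -- allow individual cells to be
segmented in 3D and measured. This package implements the quantification
chain downstream of image acquisition: per-cell morphometry, mask quality
control, and the statistics used to compare depots, plus a synthetic tissue
generator that makes the whole chain testable against known ground truth.

The default voxel grid is isotropic 1.15 um, matching typical confocal
acquisition of cleared adipose tissue at 25x, with stacks a few hundred
micrometres deep. All physical quantities are micrometres; arrays use axis
order (Z, Y, X), channel `ecm` then `lipid`.

## Morphometry

For each segmented cell with volume $V$ (voxel count times voxel volume)
and surface area $A$:

* equivalent spherical diameter $d = (6V/\pi)^{1/3}$ -- the diameter of the
  sphere with the same volume, the field's standard size measure for
  non-spherical cells;
* sphericity $\psi = (36\pi V^2)^{1/3} / A$ -- 1 for a perfect sphere,
  lower for wall-constrained angular cells, invariant under uniform
  scaling.

**Surface estimator.** Sphericity is only as good as the surface estimate,
and surface estimation on binary voxel masks is estimator-dependent in a
way volume is not. We evaluated mesh-based estimators on digitized test
solids before settling on the multi-directional Crofton estimator:

* marching-cubes mesh area on the binary mask (level 0.5) overestimates a
  digitized sphere's area by ~9% regardless of radius (the staircase
  surface is longer than the smooth one), giving sphericity ~0.92 for
  spheres that should read 1.0;
* pre-smoothing the mask fixes spheres but biases flat-faced objects
  (a cube reads ~0.83 instead of 0.81);
* the Crofton formula -- counting binary transitions along 13 lattice
  directions, weighted by each direction's spherical Voronoi solid angle,
  with $S = 2\sum_t w_t (v/\ell_t) C_t$ where $C_t$ is the crossing count,
  $\ell_t$ the step length and $v$ the voxel volume -- is nearly unbiased
  on digitized spheres (error < 0.5% at radius 25 voxels) and is the
  estimator behind MorphoLibJ, the standard Fiji morphometry plugin for
  this kind of data.

We therefore use Crofton-13 throughout, with weights computed by
deterministic Fibonacci-lattice quadrature (cached per spacing) and
recorded in each table's provenance attribute. Its known weakness is
axis-aligned flat faces (a digitized cube reads ~0.88 rather than the
analytic 0.806, because the finite direction set under-samples the
projection integral for planes aligned with the grid); cells, being
randomly oriented and convex-ish, do not hit this worst case. Absolute
sphericity values should only be compared between datasets measured with
the same estimator. Raw sphericity can slightly exceed 1 for digitized
spheres (by < 0.5%); values are reported unclamped with a flag.

Centroids are voxel-centre based (0-based indices times spacing). The
border flag marks any cell with a voxel on one of the six stack faces; the
stack is treated as the fused mosaic, so per-tile boundaries are out of
scope.

## Mask quality control

Segmented masks pass three conjunctive filters, applied in the order
border -> volume -> sphericity so removals are attributed to the first
failing rule (the retained set itself is order-independent):

* masks touching the stack border are discarded (they are truncated and
  would bias both size and shape);
* masks under 5000 voxels are discarded -- at 1.15 um spacing this equals
  an equivalent diameter of ~24.4 um, i.e. the "less than 25 um" debris
  population (nuclei, fragments, vessel lumina);
* masks with sphericity under 0.35 are discarded (segmentation artifacts,
  merged wall fragments).

Both thresholds are strict ("under"): a mask with exactly 5000 voxels or
exactly 0.35 sphericity is retained. The volume threshold is deliberately
kept in voxels, not um^3, because that is how acquisition-side filtering
is specified; the um equivalent is derivable from the spacing. A manual
review hook (an exclusion list of label ids) stands in for interactive
checking.

## Segmentation

The package does not reimplement learned segmenters; externally produced
label stacks (e.g. Cellpose masks) can be ingested verbatim with
`load_labels()` and fed to the same measurement and QC stages. For a
self-contained pipeline it provides a classical seeded watershed:

1. Gaussian-smooth each channel (default sigma 1.15 um);
2. foreground = high lipid OR low ECM (Otsu thresholds by default, fixed
   values accepted; thresholds are logged on the output);
3. Euclidean distance transform of the foreground in physical units, so
   anisotropic spacing is handled;
4. seeds = h-maxima of the distance map with depth
   $h = 0.3 \times \text{expected diameter}/2$, merged when closer than
   a third of the expected diameter (defaults: 60 um in situ, 40 um ex
   situ, both exposed as parameters and interpreted in micrometres);
5. marker-controlled watershed on the negated distance map restricted to
   the foreground, 26-connectivity.

The watershed floods with a quantized bucket queue (0.25 um bins,
first-in-first-out within a bin), which makes the result deterministic
and linear-time; at the default bin width the boundary placement is
indistinguishable from exact priority ordering for wall-separated cells.
The "low ECM" disjunct admits empty regions outside the tissue into the
foreground; the resulting non-cell labels are removed by the border and
size filters downstream, which is why segmentation and QC should be
interpreted as one unit.

## Synthetic tissue generator

The generator produces ground-truth-labelled stacks that emulate the
study conditions, not the optics: no point-spread function, no spectral
bleed-through, no mosaic seams, no nuclei channel. Passing tests on
synthetic data therefore demonstrates correctness of the measurement
chain, not robustness to every acquisition artifact.

**Sizes.** Cell diameters are lognormal (or lognormal mixtures for
bimodal depots), parameterised by arithmetic mean and CV
($\sigma_{\log}^2 = \ln(1+cv^2)$, $\mu_{\log} = \ln(\bar d) - \sigma_{\log}^2/2$)
so presets can be written directly in terms of printed depot means:
visceral (VAT) 81.32 um, subcutaneous (SCAT) 63.88 um for trout, a
38/50 um mixture for C57Bl6 mouse SCAT, ~100 um for Swiss mouse SCAT. No
depot variance is printed anywhere we could anchor to, so the CVs are free
parameters of the generator: 0.30 (VAT) and 0.35 (SCAT) by default,
right-skewed unimodal densities consistent with the published density
curves.

**In situ packing.** Sphere seeds with the drawn radii are placed by
rejection sampling with centre distance at least 0.78 times the radius sum
-- neighbours interpenetrate, so the subsequent ball-clipped Laguerre
(power-diagram) assignment cuts flat contact faces between them, giving
the angular cells seen in tissue. An ECM wall (default 3.45 um) is carved
along every cell-cell interface. Because clipping and carving remove
volume, seed radii then get one or two fixed-point corrections
$r \leftarrow r\,(V_{target}/V_{measured})^{1/3}$ (capped at 20% cumulative
growth); after correction, per-cell equivalent diameters track their drawn
targets to about 1% in the mean. The bulk fill fraction (drawn cell volume
over box volume) defaults to 0.70.

Cells are placed wholly inside the stack (the placement margin reserves
the correction headroom). Real stacks truncate cells at their borders;
simulating that would censor the ground truth and, with ~300 cells per
stack, the border filter would remove nearly half the cells with a
size-dependent bias of several percent -- making the generator useless for
calibrating mean recovery. Border handling is instead exercised by
dedicated fixtures. This is the one deliberate departure from realism in
the geometry.

**Ex situ packing.** Non-touching digitized spheres (rejection sampling
with a guaranteed gap of at least one voxel), emulating extracted cells
that round up in suspension.

**Rendering.** ECM channel: bright shell along each cell boundary (the
carved walls plus a thin rim at free surfaces); lipid channel: uniform
interior. Both decay with depth as $e^{-z/L}$ ($L$ = attenuation length)
and receive additive Gaussian noise (clipped at zero) over a constant
background. The mounting-medium contrast is modelled purely through $L$:
an index-matched clearing medium versus PBS is a 2.5-fold longer $L$
(125 um vs 50 um by default), which reproduces the 2-3x deeper usable
imaging range reported for cleared adipose tissue.

**Cohorts.** `cohort_design()` builds a sample sheet (subjects x tissues,
alternating sexes, two body-weight batches of 750 g and 1100 g, one
deterministically derived seed per sample); `generate_cohort()` writes
stacks, ground-truth labels and tables plus a JSON manifest. Every
stochastic step derives its stream from the per-sample master seed, so
cohorts are byte-reproducible.

## Distribution statistics

Kernel density estimates use a Gaussian kernel on a 512-point grid over
the data range plus three bandwidths, with the Silverman rule-of-thumb
bandwidth $0.9\min(s, IQR/1.34)n^{-1/5}$ -- the default of `geom_density()`
-- so curves are directly comparable with standard density plots.

Depot distributions are compared with a permutation two-sample
Kolmogorov-Smirnov test: $D$ is the sup-norm ECDF distance evaluated at
the pooled distinct values (tie-safe), computed in exact integer
arithmetic as $\max|c_1 n_2 - c_2 n_1| / (n_1 n_2)$ -- $D$ is a lattice
statistic, and under the null a large probability mass ties the observed
value exactly, so floating-point accumulation would silently drop those
ties from the exceedance count and bias $p$ low; the pool is randomly re-split
10,000 times into the original group sizes; and the p-value uses the
Phipson-Smyth estimator $p = (b+1)/(m+1)$, counting ties as exceedances,
so p is never zero and its floor at $m = 10^4$ is $1/10001$. The
comparison pools cells across samples within a depot (matching how pooled
distribution curves are drawn); per-sample densities are also available.
Whether permutation should re-split at the cell or the subject level is a
design fork; cell-level is implemented, subject-level resampling would be
the conservative extension for strongly clustered data.

Depot, sex and body-weight effects are fitted by ordinary least squares on
**per-sample mean** diameter or sphericity, not per-cell values: with
thousands of cells per sample, per-cell fits would pseudo-replicate and
overstate significance. The per-sample choice is recorded in the output.
p-values are t-based per coefficient.

## Numerical choices and degenerate inputs

* Thresholding: Otsu on a 256-bin histogram; constant images yield an
  empty foreground (and zero labels) rather than an error.
* Empty inputs: an empty label stack measures to an empty table; QC of an
  empty table is an empty table; `sample_diameters(n = 0)` is an empty
  vector. Non-positive volumes, surfaces, means or CVs are domain errors.
* Geometry errors (a cell that cannot fit, or placement that cannot
  finish within the retry budget) report how many cells were placed.
* Determinism: every stochastic operation is a pure function of its
  inputs and an integer seed; RNG state is saved and restored around each
  draw, so package calls never perturb the caller's RNG stream.
* Labels are written as 16-bit TIFF pages (exact round trip up to 65535
  labels); intensities as 16-bit with values clipped to [0, 1].

## Problem sizes

The bundled analysis scripts and the test suite run at desk scale: demo
samples of 12-60 cells, recovery runs of 300 cells per depot at the full
1.15 um grid (~10^8 voxels per stack), and a 24-sample cohort simulated at
a 2.3 um grid -- at 2.3 um the voxelization error on a 60-80 um cell's
equivalent diameter is below 1%, immaterial for per-sample means, while
the cohort runs an order of magnitude faster. These sizes are the
package's own validation choices; the functions themselves take arbitrary
stack sizes.

## Known limitations

* Absolute sphericity is estimator-dependent; cross-study comparisons
  must match estimators (Crofton-13 here).
* The generator's cells are convex-ish; real adipocytes can be locally
  concave where several neighbours meet, so in situ sphericity in real
  tissue is lower than in synthetic tissue at the same packing.
* No optical realism (PSF, bleed-through, stitching seams); segmentation
  robustness to those must be assessed on real data, e.g. by ingesting
  externally produced masks.
* The watershed stand-in is tuned for wall-separated cells; heavily
  merged foregrounds (weak ECM signal) will under-segment.
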