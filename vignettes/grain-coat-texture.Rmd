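---
title: "Grain-coat texture phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grain-coat texture phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graintex)
```

## Scope

`graintex` measures the surface texture of cereal grains in white-background
plate photographs and runs the panel-level statistics such data support:
trait clustering, PCA, ANOVA factor contributions, year-trend and
germination-association tests with randomization null bands. This vignette
explains the models behind each stage, the parameters that matter, the
numerical conventions, and what the synthetic data generator does and does
not emulate.

## The texture model

Texture is computed on the BT.601 grayscale image
(`gray = round(0.299 R + 0.587 G + 0.114 B)`, half-up), quantized into `G`
uniform levels by `level = floor(gray * G / 256)`.

**Gray-level co-occurrence (GLCM).** For each of the 8 unit offsets
(horizontal, vertical, both diagonals, and their opposites) at distance
`d` pixels, every ordered pair of in-mask pixels is counted; counts are
summed over offsets and normalized. Because each offset's opposite is also
counted, `P` is symmetric by construction, and summing the 8 directions
before computing features ("omnidirectional" accumulation) makes every
descriptor invariant to 90-degree rotation of the image. Ten descriptors
are derived from `P` (mean, variance, uniformity, entropy, homogeneity,
inertia, correlation, cluster shade, cluster prominence, maximum
probability); `glcm_features()` documents each formula.

**Gray-level run lengths (GLRM).** Maximal constant-level segments of
consecutive in-mask pixels are collected along the 4 scan orientations
(0, 45, 90, 135 degrees; a run read forward or backward is the same run,
so 8 directions collapse to 4). Out-of-mask pixels break runs. Every
in-mask pixel belongs to exactly one run per orientation, giving the
conservation law `sum(l * r(g, l)) = 4 * n_pixels` that the tests assert
exactly. Six descriptors follow (`glrm_features()`).

Key parameter choices:

* **`G = 32` gray levels (default, configurable).** Grains of a few
  thousand pixels need enough levels for sensitivity but not so many that
  the co-occurrence matrix becomes an identity-like sparse matrix; 32 is
  the usual compromise for regions of 10^3 to 10^4 pixels.
* **GLCM distance `d = 1`.** Only neighboring-pixel interactions are
  modeled; larger distances are exposed but untested territory.
* **Homogeneity** uses the inverse-difference-moment form
  `1/(1 + (i - j)^2)`; **entropies** use log base 2. These are stated
  conventions — published feature lists differ in denominator and base,
  and the choice is documented rather than configurable.
* **Degenerate contracts.** A region with no valid neighbor pair raises a
  degenerate-region error (the caller drops the grain and logs it). GLCM
  correlation is defined as 0 when the marginal variance is 0 (a constant
  patch has no linear structure to correlate); this differs from the
  limit-based convention of 1 used by some libraries and is covered by
  tests.
* **Run ratio** is normalized by `n_orientations * n_pixels`, keeping its
  range `(0, 1]` after orientation pooling.

**Color means.** Per-grain arithmetic means of RGB, HSV, CIELAB (sRGB
under D65) and full-range BT.601 YCbCr channels. Hue is averaged
circularly (vector mean of angles): an arithmetic mean would be wrong for
grains whose hues straddle the 0/360 wrap.

**Outlier filter.** Following standard practice for grain panels, a grain
is excluded when any texture trait deviates from the column mean by more
than `k = 3` SD. Means and SDs are computed once on the unfiltered table
(single pass, no iteration), and a zero-SD trait contributes `z = 0`.

## Segmentation

Plates are thresholded globally (Otsu on the gray histogram; foreground =
darker than threshold), opened once with a radius-1 structuring element to
shed threshold speckle, and labeled with 8-connectivity. Components
smaller than `min_area = 200` px² are dropped, as are border-touching
components when `exclude_border` is set. Coordinates are 0-based,
row-major, half-open. Physical scale (mm/px) is deliberately not computed:
all 16 texture descriptors are scale-free ratios of counts.

## The statistics suite

* **Correlation matrix and trait tree.** Pearson correlations over grains
  (default) or per-genotype means. The trait distance is `d = 1 - |r|`
  (anticorrelated traits are similar, as both carry the same information)
  with `d = 1 - r` available as a variant. UPGMA (average linkage) builds
  the tree; merge heights are reported on the ultrametric scale
  (tip-to-node = merge distance / 2), the convention phylogenetic software
  uses for Newick output. Traits are sorted lexicographically before
  clustering so ties break deterministically. `cut_clusters()` merges at
  heights `<= h` (the `stats::cutree` convention; the boundary case of an
  exactly-zero-height tree cut at `h = 0` therefore yields one cluster,
  not singletons).
* **PCA** standardizes each trait and eigendecomposes the correlation
  matrix; component signs are fixed so the largest-magnitude loading is
  positive, making outputs reproducible across linear-algebra backends.
* **ANOVA.** Classic one-way fixed-effects F per trait, once per factor
  (genotype, year). `MS_within = 0` with distinct group means returns the
  sentinel `F = Inf, p = 0`; identical group multisets return
  `F = 0, p = 1`. Significance is a two-decision flag at 0.05. No
  multiple-testing correction is applied anywhere in the suite: the
  year-trend and germination procedures use extreme-value null bands as
  their guard, and adding a correction on top would change the decision
  rule the suite is built around.
* **Year encodings.** 2003 → (0, 2003, 1), 2004 → (0, 2004, 2),
  2009 → (1, 2009, 3), 2014 → (1, 2014, 4) for (Year01, Year, YearRank);
  other years require an explicit mapping.
* **Null bands.** `null_band()` reshuffles the trait (permutation) or
  resamples it with replacement (bootstrap), holding the covariate fixed,
  and returns the min/max of the replicate correlations (default 2000).
  An observed correlation outside the extremes of *both* tests is flagged
  significant — a rule that is never more liberal than either band alone.
  Bands for the year-trend table are computed once per trait against the
  rank-coded year (the most conservative covariate) and applied to all
  three encodings; per-encoding bands are a configuration option.
* **Germination association.** Germination is year-centered (the year
  main effect dominates storage panels), centered values beyond 3 SD are
  removed (the same `k` as the grain filter, adopted for symmetry since no
  published rule exists), and each trait is z-scored within genotype —
  removing genotype-level signal so the test isolates the within-line
  association; pooled z-scoring is available as an option.

## The synthetic generator

`render_grain()` draws an elliptical grain whose in-mask intensity is

```
base_gray - shading_depth * r^2 + roughness + wrinkle
```

with `r` the normalized elliptical radius (parabolic rim shading emulating
3-D curvature), `roughness` a white-noise field smoothed by a Gaussian
kernel of SD `roughness_scale` px and rescaled to SD `roughness_amp`
(band-limited noise is the minimal model that moves the GLCM descriptors
smoothly between "smooth" and "rough"), and `wrinkle` a sinusoid of
amplitude `wrinkle_amp` and frequency `wrinkle_freq` ridges per 100 px in
the grain's own frame — phase varying across the major axis for
`wrinkle_axis = "along"` (ridges run along the grain) or along it for
`"across"` (transverse folds). Color is the base RGB shifted by the
intensity deviation, which keeps the luma equal to the gray channel but
also means hue and the YCbCr chroma channels are constant by construction:
synthetic panels exercise the color *machinery*, not color variation, and
the correlation step rightly excludes those constant columns.

`render_plate()` places grains at random non-overlapping positions
(bounding boxes separated by `min_gap`, nothing touching the border) on a
250 ± 2 near-white background — noisy enough to keep Otsu segmentation
honest, far from defeating it. All randomness flows from one master seed
through named substreams (`substream_seed(seed, "grain.3")` etc.), so
adding grains or plates never perturbs earlier ones and every output is a
pure function of (config, seed).

`generate_panel()` builds the multi-year design: per-grain texture
parameters are `global mean + genotype effect + year_slope * yearRank +
grain noise`, with genotype effects drawn once per genotype. Defaults —
44 genotypes, years 2003/2004/2009/2014, 20 grains per cell, base
roughness 14 with year-rank slope −2, genotype SDs of 8/3/3 gray units on
base gray, roughness and wrinkle amplitude — encode a panel in which later
harvests (shorter genebank storage) are smoother, with both genotype and
year contributing to every texture trait. The base/slope pair keeps all
cell means comfortably positive so the non-negativity clamp on amplitudes
almost never binds. `generate_germination()` produces per-cell rates
`plogis(intercept + year offset + linkage * z(trait) + noise)` — a year
main effect, no genotype effect, and an optional weak trait link.

What the generator does *not* emulate: real grain outlines (ellipses with
axis jitter stand in for them), photometric calibration targets,
non-stationary illumination, touching grains, and any quantitative match
to real wheat texture scales — no published measurements of those scales
exist, so the defaults are calibrated to exercise the feature space, not
to mimic wheat. Passing tests therefore demonstrate correctness of the
machinery and recoverability of injected structure, not accuracy on
photographs.

## Simulation experiments and problem sizes

Two packaged experiments connect the generator to the statistics:

* **`null_band_experiment(n, ...)`** reproduces the magnitude of the
  randomization bands, which depends only on sample size and replicate
  count: at `n = 3460` the 2000-replicate permutation band is ≈ ±0.06; at
  `n = 1279` ≈ ±0.097 (the expected maximum of 2000 draws of a null
  correlation, `≈ 3.46 / sqrt(n - 1)` by the Gumbel approximation).
  Extremes are averaged over 20 seeds in the acceptance script.
* **`pca_recovery_experiment()`** renders 40 genotypes × 12 grains whose
  surfaces vary in two independent factors — roughness amplitude
  (uniform on 0–18) and wrinkle orientation (along/across, ±1) — and runs
  the trait PCA on genotype-mean features. Two design choices matter and
  were fixed a priori. First, orientation is visible to omnidirectional
  features on randomly rotated grains only through period-versus-chord
  truncation, so the wrinkle frequency is low (3 ridges / 100 px: one
  ridge period exceeds the grain width, and along-axis ridges sample less
  of the sinusoid than transverse folds). Second, genotype means are used
  instead of single grains: the orientation mode is the weaker of the
  two, and the second principal axis aligns with it cleanly only when
  per-observation noise is small relative to both modes. With these
  choices PC1 scores correlate |r| > 0.9 with roughness and PC2 scores
  |r| > 0.85 with orientation, with cross-correlations below 0.25.

Problem sizes used by the test suite were chosen to keep the full run
around two minutes while leaving the statistical checks well-powered:
ANOVA power and type-I simulations run 100 and 400 replicates of an
8-genotype × 4-year × 5-grain panel on the generator's fast
(non-rendering) path — the ANOVA consumes trait columns, so rasterizing
every replicate would add nothing; texture-oracle equivalence uses 200
random masked patches of sizes 4–12 at `G ∈ {2, 4, 8}`; the end-to-end
determinism check renders a 6-genotype × 5-grain panel twice and compares
output bytes.

## Known limitations

* Touching grains are not split (no watershed); the generator never
  produces them, and real plates with clumped grains will under-segment.
* The within-genotype trait standardization in the germination procedure
  removes genotype-mediated associations by design; a trait link acting
  purely through genotype means is invisible to it (the pooled option
  exists for that case).
* The `d = 1 - |r|` distance bounds tree heights at 0.5 on the
  ultrametric scale; cluster-cut heights quoted on other scales (e.g.
  from software plotting full merge distances, or the `1 - r` variant
  reaching 1.0) are not comparable — both variants are implemented so the
  discrepancy surfaces instead of being silently resolved.
* Grayscale conversion, color-space formulas and the feature conventions
  above are fixed choices; pipelines built on different conventions will
  produce systematically shifted (though typically rank-preserving)
  trait values.
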