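---
title: "Cluster-wise quantile normalization of multi-batch cytometry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-wise quantile normalization of multi-batch cytometry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large cytometry studies rarely fit on a single barcoded plate. Samples
processed in different batches — different days, stainings, thawing
cycles, instrument states — acquire systematic shifts in marker
intensity. These batch effects have two properties that defeat the
normalization strategies inherited from bulk assays:

1. **They are nonlinear in expression level.** The negative peak of a
   marker may sit still while its positive peak wanders, so no affine
   rescaling can align whole distributions.
2. **They are cell-type specific.** Two populations can sit at the same
   intensity on a marker yet be shifted by different amounts, because
   the technical artefact interacts with how much protein each cell
   type carries.

`cytoqnorm` removes such batch effects under one experimental design
assumption: **every batch carries an aliquot of the same control
material**. Whatever happened to the batch happened to its control, so
the control pins down the batch's distortion, and the distortion —
learned on the control — can be reversed on every other sample of that
batch. A second, blinded control aliquot per batch (a *validation*
sample) lets the correction be scored honestly.

## The model

Write $x$ for arcsinh-transformed intensities, $\mathrm{asinh}(x/c)$
with cofactor $c = 5$ (the mass-cytometry standard; all modeling
happens on this scale). The pipeline, per batch $b$:

1. **Cluster** the pooled control cells into metaclusters
   $j = 1,\dots,k$ with a self-organizing map (many small node
   clusters) followed by consensus hierarchical metaclustering of the
   node codebook. Clustering is deliberately *rough*: it only needs to
   separate the major cell lineages, whose technical shifts differ.
2. **Describe** each control's distribution by empirical quantiles
   $q^{(b)}_{j,m}(p)$ at 101 probabilities $p = 0, 0.01, \dots, 1$ for
   every metacluster $j$ and marker $m$.
3. **Choose a goal** $g_{j,m}(p)$: the across-batch mean of the control
   quantiles (default), or one designated batch's quantiles.
4. **Fit one monotone map per (batch, metacluster, marker)**: a
   monotone cubic Hermite spline (Fritsch–Carlson tangents) through the
   points $\bigl(q^{(b)}_{j,m}(p),\, g_{j,m}(p)\bigr)$, with anchor
   knots $(0,0)$ and $(8,8)$ added to curb extrapolation.
5. **Apply**: every cell of every sample in batch $b$ is assigned to its
   metacluster (nearest SOM node over the clustering markers) and each
   normalized marker value is passed through the corresponding spline.

Because each map is monotone, within-sample rankings are preserved —
the normalization reorders nothing, it only re-scales.

The critical assumption is that *clusters themselves are stable across
batches*. This is checked by the cluster-frequency CV: the fraction of
cells per metacluster is computed for every control, and the
coefficient of variation (sample sd / mean) across controls is taken
per cluster. A maximum CV above 2 signals clusters that exist only in
some batches, i.e. clustering has itself been captured by the batch
effect; `train_model()` then warns (or errors with `strict = TRUE`) and
the analyst should reduce `k` — in the limit `clustering = FALSE`
(k = 1), which degrades gracefully to plain quantile normalization.

## Evaluation: binned EMD and the reduction score

Aligning distributions is scored with the 1-D Earth Mover's Distance on
histograms with 0.1-wide bins of the arcsinh scale. For a population
$p$ and marker $m$, all pairwise EMDs between batches are computed and
the maximum taken:
$\mathrm{EMD}_{p,m} = \max_{i,j} \mathrm{EMD}(\mathrm{batch}_i, \mathrm{batch}_j)$.
The reduction score is

$$\mathrm{Reduction}_{p,m} = \frac{\mathrm{EMD}^{\mathrm{orig}}_{p,m} -
\mathrm{EMD}^{\mathrm{norm}}_{p,m}}{\mathrm{EMD}^{\mathrm{orig}}_{p,m}},$$

averaged over the pairs where either EMD exceeds 2 — pairs below 2 on
both sides were never materially affected and would only dilute the
score. Negative reductions flag pairs the normalization made *worse*.

EMD is reported in **bin units** (ground distance 1 between adjacent
bins), so the exclusion threshold of 2 corresponds to 0.2 arcsinh
units of transport. This convention makes the threshold and the
distances directly comparable; `bin_width` is a parameter throughout.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cofactor` | 5 | arcsinh divisor; raw scale is `cofactor * sinh(y)` |
| `xdim`, `ydim` | 10 × 10 | SOM grid; ~4× more nodes than expected lineages |
| `k` | 25 | metaclusters; must pass the CV check (max CV ≤ 2) |
| `n_quantiles` | 101 | quantile grid 0, 0.01, …, 1 |
| `goal` | `"mean"` | across-batch mean, or a batch id |
| `anchors` | `c(0, 8)` | spline anchor knots (0,0) and (8,8) |
| `min_cells` | 50 | below this per (batch, cluster), the map is the identity |
| `total_cells` | 1e6 | SOM training subsample across all controls |
| `epochs`, `som_alpha` | 10, 0.05→0.01 | online SOM schedule |
| `n_resamples`, `subsample_frac` | 100, 0.9 | consensus metaclustering |
| `cv_threshold` | 2 | cluster-stability alarm |
| `bin_width` | 0.1 | EMD histogram bins (arcsinh units) |

## Numerical choices

* **Quantile definition.** Linear interpolation of order statistics
  (type 7, the common statistical default): p = 0 is the minimum, p = 1
  the maximum.
* **Monotone tangents.** Tangents start as averaged secant slopes and
  are projected onto the Fritsch–Carlson monotonicity region. The
  classic single sequential sweep is *not* sufficient: repairing
  interval $k$ rescales the tangent it shares with interval $k-1$ and
  can push that pair back outside its region, which yields small
  non-monotone dips (the widely used reference implementation of this
  scheme exhibits dips up to ~1e-3 on adversarial monotone knot sets).
  `cytoqnorm` iterates the sweep to its fixed point; convergence is
  guaranteed because any pair outside the region is also outside the
  radius-3 circle, so each projection strictly shrinks tangents. Where
  a single sweep suffices, the two schemes agree to floating-point
  precision, and the test suite checks both this agreement and
  unconditional monotonicity.
* **Duplicate knots.** A marker that is 0 (or constant) for many cells
  produces runs of equal quantiles. Runs of x-knots within 1e-10 are
  collapsed to one knot carrying the mean of their y-values, keeping
  `knots_x` strictly increasing as the Hermite scheme requires. Fewer
  than two distinct knots degrade to the identity with a warning.
* **Anchors and monotonicity.** Anchor points are only inserted outside
  the data range, and their y-values are clamped to the monotone
  envelope of the data knots — arcsinh values can be slightly negative,
  and a blind (0,0) insertion could otherwise break monotonicity of the
  y-sequence.
* **Extrapolation.** Beyond the outermost knots the spline continues
  linearly with slope 1. The anchors exist to curb extrapolation inside
  [0, 8]; slope-1 continuation extends the same intent below 0 and
  above 8. The two-quantile linear variant instead extends its own
  line, which is exactly what makes it fragile outside the quantile
  pair.
* **Ties in cell assignment.** A cell equidistant to several SOM nodes
  goes to the lowest node index.
* **Sparse clusters.** A (batch, cluster) with fewer than `min_cells`
  cells gets identity transformations rather than noise-fit splines; a
  metacluster empty in *all* controls has an undefined CV, reported as
  missing rather than 0.
* **Determinism.** Every stochastic step (subsampling, SOM
  initialization and update order, consensus resampling, synthetic
  generation) draws from seeds derived from one master seed, without
  touching the caller's RNG state. Equal seeds give byte-identical
  model archives and output FCS files.

## Design choices where the method is open

* **SOM schedule.** Online training, rectangular grid, bubble
  neighbourhood with a strict radius cutoff (initial radius = half the
  grid diagonal, decaying linearly to 1, so the final phase updates
  only the best-matching unit), learning rate 0.05 → 0.01. These mirror
  common SOM practice in cytometry; all are exposed as parameters.
* **Consensus metaclustering.** 100 resamples of 90% of the nodes,
  average-linkage hierarchical clustering per resample, final labels by
  average-linkage on 1 − consensus. The procedure's contract (stable
  grouping of codebook nodes into k metaclusters) matters more than
  its internals; parameters are exposed.
* **Multiple controls per batch** (e.g. stimulated + unstimulated) are
  concatenated before quantile computation, so the training material
  spans the widest available expression range — the remedy for the
  range-coverage failure mode demonstrated by the `range_gap` preset.
* **FCS dialect.** Files are written as FCS 3.1, `$DATATYPE=F` (32-bit
  float), list mode — lossless for normalized fractional values. The
  reader accepts FCS 3.0/3.1 with float, double or uniform integer
  data in either byte order. Acquisition keywords are preserved where
  possible; structural keywords are regenerated on write. Spillover/
  compensation handling is out of scope (mass cytometry context), and
  channels excluded from the transform spec (e.g. `Time`,
  `Event_length`) pass through every stage unmodified.

## The synthetic data generator

Real multi-batch control data cannot ship with a package, so
`cytoqnorm` generates its own study designs with known ground truth.
`synthetic_spec()` describes a mixture of cell populations (per-marker
truncated-normal profiles on [−0.5, 8], respecting the anchor range),
replicated across batches as a control + validation aliquot pair, where
each batch applies strictly monotone distortions per marker — affine,
sigmoid (expression-level-dependent), power warps, or piecewise-linear
— optionally restricted to single populations. Control and validation
aliquots of a batch share its distortions: the design premise that all
samples of a batch underwent the same shifts. Distortions are validated
for strict monotonicity at specification time.

`make_default_specs()` freezes five study conditions (4 populations,
4 markers, 3 batches, 8,000 cells per aliquot — 48,000 cells per
preset, sized so the median of the smallest population is estimable to
~0.015 arcsinh units while the suite still runs in seconds):

* `flat` — no effects; the trained model should be near-identity and
  the cluster-frequency CVs small.
* `global_shift` — opposite affine shifts of one marker in batches 2
  and 3 (±0.5), affecting all populations equally.
* `cluster_specific` — the same marker shifted in opposite directions
  in two different populations (±0.6), which no single global map can
  undo: the cluster-free variant (k = 1) must do strictly worse.
* `nonlinear` — a sigmoid shift (±0.6 centred at 3): the positive peak
  moves while the negative peak stays put, so the two-quantile linear
  map must do strictly worse than the 101-quantile spline.
* `range_gap` — the controls lack the high-expression population that
  the validation samples carry, and the batch distortion differs
  between the low and the high range. A model trained on such
  range-deficient controls extrapolates wrongly and *increases* at
  least one population-marker distance; clearing `control_weights`
  (pooling the full-range material into the controls, the analogue of
  combining stimulated and unstimulated controls) resolves it.

For the `range_gap` analyses, k = 3 metaclusters are used — the number
of populations the *controls* exhibit. With a spare fourth cluster the
withheld population is absorbed by a nearly empty metacluster that
receives the identity transform, which would mask precisely the
extrapolation hazard the preset exists to demonstrate; sizing k from
what the controls show is also how the method is applied in practice.

What the generator deliberately does **not** emulate: detector count
noise (Poisson ion statistics), spillover between channels, doublets,
debris, acquisition-time drift within a sample, or correlations between
markers within a population. Passing tests on these presets therefore
demonstrates that the algorithm recovers the *structure* of batch
effects it models — monotone, cluster-specific, expression-dependent
shifts — not that it is robust to every artefact of real acquisitions.

## Problem sizes in the test suite

The packaged tests and the acceptance script run the pipeline with a
6 × 6 SOM grid, k = 4 metaclusters (3 for `range_gap`) and 9,000
aggregated training cells on the synthetic presets — a scaled-down
analogue of the 10 × 10 grid / 25 metaclusters / 1M-cell configuration
that `norm_params()` defaults to for real panels. The scaled
configuration keeps roughly the same ratio of nodes to populations.

## Known limitations

* The whole construction assumes batch-to-batch variation dominates
  aliquot-to-aliquot variation of the control material; the CV check
  tests a necessary condition, not a sufficient one.
* Controls must span the expression range of the samples of interest;
  the `range_gap` preset shows what happens when they do not. Splines
  are anchored, but anchoring cannot conjure information about ranges
  the controls never visited.
* Markers are normalized independently per cluster; joint cross-marker
  distortions are not modeled.
* Batches not seen at training cannot be normalized (this is an error,
  not a silent identity).
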