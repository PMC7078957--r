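# cytoqnorm

Cluster-wise quantile normalization of multi-batch cytometry data.

## The problem

Mass and flow cytometry studies that span multiple barcoded plates or
acquisition days pick up **batch effects**: systematic intensity shifts
shared by all samples processed together. These shifts are awkward in
two specific ways — they are *nonlinear* in expression level (a
marker's negative peak can sit still while its positive peak drifts)
and they are *cell-type specific* (two populations at the same
intensity can shift by different amounts). Global per-sample alignment
methods flatten biology along with technics.

`cytoqnorm` is for studies that include an **aliquot of the same
control material on every batch**. The batch's distortion is learned on
its control and reversed on every other sample of the batch:

1. Cells of all controls are clustered — a self-organizing map into
   many small node clusters, then consensus hierarchical metaclustering
   into *k* metaclusters — with a coefficient-of-variation check that
   the clusters themselves are batch-stable (max CV ≤ 2).
2. Per batch *b*, metacluster *j* and marker *m*, the control's
   empirical quantiles `q_bjm(p)` are computed at `p = 0, 0.01, …, 1`.
3. A goal distribution `g_jm(p)` is fixed: the across-batch mean of
   control quantiles, or one designated batch.
4. A monotone cubic Hermite spline (Fritsch–Carlson tangents) is fit
   through `(q_bjm(p), g_jm(p))`, anchored at (0,0) and (8,8) on the
   arcsinh scale (cofactor 5).
5. Any sample of batch *b* is normalized by assigning each cell to its
   metacluster and passing each marker value through the corresponding
   spline.

Results are scored with the binned 1-D Earth Mover's Distance (0.1-wide
bins, pairwise maximum over batches per population and marker) and the
**reduction score** `(EMD_before − EMD_after)/EMD_before`, averaged over
the population-marker pairs whose EMD exceeds 2 bin units on either
side.

The package also ships FCS 3.0/3.1 reading and FCS 3.1 writing, the
arcsinh transform layer, a two-quantile linear alternative and a
cluster-free (k = 1) variant for comparison, and a synthetic multi-batch
generator with ground-truth population labels and monotone,
population-specific distortions for testing the whole pipeline without
any external data.

## Worked example

Simulate a three-batch study in which batches 2 and 3 shift Marker1 by
±0.5 arcsinh units, train on the control aliquots, normalize the
blinded validation aliquots, and score the alignment:

```r
library(cytoqnorm)

spec <- make_default_specs(seed = 7)$global_shift
ds <- generate_dataset(spec)

controls   <- synthetic_controls(ds)       # batch -> control cells
validation <- synthetic_validation(ds)     # batch -> blinded aliquot
labels     <- synthetic_validation_labels(ds)

model <- train_model(controls,
                     norm_params(xdim = 6, ydim = 6, k = 4,
                                 total_cells = 9000, seed = 1))
model
#> <normalization_model> 3 batches (batch1, batch2, batch3), 4 metacluster(s), 4 markers, method = spline
#>   SOM 6x6, goal = mean of batches, max cluster CV = 0.0357

normed <- lapply(names(validation), function(b)
  normalize_sample(validation[[b]], b, model))
names(normed) <- names(validation)

markers <- paste0("Marker", 1:4)
before <- max_pairwise_emd(validation, labels, markers)
after  <- max_pairwise_emd(normed, labels, markers)

round(before$emd_max, 2)
#>           marker
#> population Marker1 Marker2 Marker3 Marker4
#>       Pop1   10.05    0.09    0.12    0.10
#>       Pop2    9.91    0.19    0.17    0.15
#>       Pop3    9.97    0.18    0.22    0.18
#>       Pop4    9.89    0.19    0.38    0.26

round(after$emd_max, 2)
#>           marker
#> population Marker1 Marker2 Marker3 Marker4
#>       Pop1    0.41    0.13    0.14    0.11
#>       Pop2    0.18    0.13    0.34    0.14
#>       Pop3    0.12    0.33    0.31    0.21
#>       Pop4    0.63    0.42    0.42    0.40

reduction_score(before, after)
#> <reduction_report> score = 0.9662 (sd 0.02359) over 4 included population-marker pairs
```

Reading the numbers: before normalization, every population's Marker1
distributions sit ~10 bin units (1.0 arcsinh unit — the injected ±0.5
shift) apart between the worst batch pair, while the unshifted markers
are already aligned (EMD < 0.4, i.e. sampling noise). After
normalization the Marker1 distances drop below 0.7 bin units; the four
affected (population, marker) pairs — the only ones whose EMD exceeded
the threshold of 2 — recover on average 96.6% of their original
distance. The max cluster CV of 0.036 confirms the metaclusters were
stable across batches, so the per-cluster quantile maps were trustworthy.

Normalized samples can be written back to standard FCS files:

```r
raw <- invert_transform(normed[["batch2"]], model$transform)
write_fcs(raw, "Norm_batch2_validation.fcs")
```

A thin command-line front-end over the same functions (subcommands
`train`, `normalize`, `evaluate`, `simulate`) lives at
`inst/scripts/cytoqnorm-cli.R`; the methods vignette
(`vignettes/cluster-quantile-normalization.Rmd`) documents the model,
its parameters, numerical choices and limitations.

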