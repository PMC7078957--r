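# The synthetic multi-batch generator: validation, determinism, ground
# truth consistency and file output.

test_that("spec validation rejects bad mixtures and non-monotone distortions", {
  means <- rbind(c(1, 5), c(4, 2))
  expect_error(synthetic_spec(means, c(0.5, 0.4)), "sum to 1")
  expect_error(synthetic_spec(means, c(0.5, 0.5), control_weights = c(1, 0.5)),
               "sum to 1")
  expect_error(synthetic_spec(means, c(0.5, 0.5), aliquots_per_batch = 1),
               "2 aliquots")
  # a sigmoid shift too steep to stay increasing is rejected up front
  expect_error(
    synthetic_spec(means, c(0.5, 0.5), batch_effects = list(
      list(batch = 2, marker = 1, fun = distort_sigmoid(-10, 3, 0.5)))),
    "strictly increasing")
  expect_error(distort_affine(a = -1), "positive slope")
  expect_error(distort_piecewise(c(0, 1, 2), c(0, 2, 1)),
               "strictly increasing")
  # plain functions are not accepted as effects (no monotonicity contract)
  expect_error(
    synthetic_spec(means, c(0.5, 0.5), batch_effects = list(
      list(batch = 2, marker = 1, fun = function(x) x + 1))),
    "distort_")
})

test_that("distortion families transform as specified", {
  f <- distort_affine(1.2, -0.3)
  expect_equal(f(c(0, 5)), c(-0.3, 5.7))
  g <- distort_sigmoid(0.6, center = 3, width = 0.7)
  expect_equal(g(3), 3 + 0.3)             # half the shift at the center
  expect_lt(g(-0.5) - (-0.5), 0.01)       # negative end essentially fixed
  expect_gt(g(8) - 8, 0.59)               # positive end fully shifted
  p <- distort_power(2)
  expect_equal(p(-0.5), -0.5)
  expect_equal(p(8), 8)
  w <- distort_piecewise(c(0, 4, 8), c(0, 5, 8))
  expect_equal(w(c(0, 2, 4, 8)), c(0, 2.5, 5, 8))
  expect_equal(w(9), 9)                    # slope-1 continuation
})

test_that("generation is deterministic and labels align with rows", {
  spec <- make_default_specs(seed = 3)$global_shift
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(lapply(d1$samples, function(s) s$data$values),
                   lapply(d2$samples, function(s) s$data$values))
  expect_identical(lapply(d1$samples, `[[`, "labels"),
                   lapply(d2$samples, `[[`, "labels"))
  s <- d1$samples[["batch1_control"]]
  expect_identical(length(s$labels), n_cells(s$data))
  # per-population means of the undistorted batch match the spec profile
  for (p in rownames(spec$pop_means)) {
    idx <- s$labels == p
    got <- colMeans(s$data$values[idx, ])
    expect_lt(max(abs(got - spec$pop_means[p, ])), 0.06)
  }
  # undistorted values respect the truncation range
  expect_true(all(s$data$values >= -0.5 & s$data$values <= 8))
})

test_that("control and validation aliquots of a batch share distortions", {
  spec <- make_default_specs(seed = 13)$nonlinear
  ds <- generate_dataset(spec)
  ctl <- synthetic_controls(ds)
  val <- synthetic_validation(ds)
  bm <- function(m) bin_values(m$values[, "Ch1"])
  # aliquots of one batch differ only by sampling noise; aliquots of
  # different batches differ by the injected distortion
  same_batch <- emd_1d(bm(ctl[["batch2"]]), bm(val[["batch2"]]))
  cross_batch <- emd_1d(bm(ctl[["batch2"]]), bm(val[["batch3"]]))
  expect_lt(same_batch, 1)
  expect_gt(cross_batch, 3)
})

test_that("control-specific weights withhold populations from controls only", {
  spec <- make_default_specs(seed = 19)$range_gap
  ds <- generate_dataset(spec)
  ctl_lab <- lapply(Filter(function(s) s$role == "control", ds$samples),
                    `[[`, "labels")
  val_lab <- synthetic_validation_labels(ds)
  expect_false(any(vapply(ctl_lab, function(l) "Pop4" %in% l, logical(1))))
  expect_true(all(vapply(val_lab, function(l) "Pop4" %in% l, logical(1))))
})

test_that("writing a dataset produces readable FCS, labels and a manifest", {
  spec <- synthetic_spec(rbind(c(1, 5), c(4, 2)), c(0.6, 0.4),
                         n_batches = 2, n_cells_per_sample = 400, seed = 8,
                         batch_effects = list(
                           list(batch = 2, marker = "Marker1",
                                fun = distort_affine(1, 0.4))))
  dir <- withr::local_tempdir()
  ds <- generate_dataset(spec, out_dir = dir)
  expect_identical(nrow(ds$files), 4L)
  expect_true(all(file.exists(ds$files$file)))
  # FCS round trip: raw file values match the arcsinh data inverse-transformed
  s <- ds$samples[["batch2_validation"]]
  disk <- read_fcs(file.path(dir, "batch2_validation.fcs"))
  expect_equal(asinh(disk$values / 5), s$data$values,
               ignore_attr = TRUE, tolerance = 1e-5)
  labs <- utils::read.csv(file.path(dir, "batch2_validation_labels.csv"))
  expect_identical(nrow(labs), n_cells(s$data))
  expect_identical(labs$population, s$labels)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(manifest$batch_effects[[1]]$family, "affine")
  expect_identical(manifest$batch_effects[[1]]$marker, "Marker1")
})
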