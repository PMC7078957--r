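# Synthetic multi-batch cytometry data with ground truth: mixtures of
# cell populations with distinct marker profiles, replicated across
# batches as control + validation aliquots, where each batch applies
# smooth, strictly monotone, optionally population-specific and
# expression-level-dependent distortions per marker. Cells are generated
# directly on the arcsinh scale (where the normalization operates) as
# truncated normals on [-0.5, 8], and inverse-transformed only when
# written to FCS.

SYNTH_RANGE <- c(-0.5, 8)

#' Monotone distortion constructors
#'
#' Parametric families of strictly increasing distortions used as
#' synthetic batch effects on the arcsinh scale:
#' * `distort_affine(a, b)`: `x -> a*x + b`, `a > 0`.
#' * `distort_sigmoid(amount, center, width)`:
#'   `x -> x + amount * plogis((x - center)/width)` — an
#'   expression-level-dependent shift that leaves one end of the range
#'   (nearly) untouched; strictly increasing when
#'   `|amount| < 4 * width`.
#' * `distort_power(gamma, lo, hi)`: monotone power warp of `[lo, hi]`
#'   onto itself, continued with slope 1 outside.
#' * `distort_piecewise(breaks_x, breaks_y)`: piecewise-linear through
#'   strictly increasing breakpoints, slope-continued outside.
#'
#' @param a,b Affine slope (positive) and offset.
#' @param amount,center,width Sigmoid shift parameters.
#' @param gamma Power exponent (> 0).
#' @param lo,hi Warp range (defaults: the generator range).
#' @param breaks_x,breaks_y Strictly increasing breakpoint vectors.
#' @return A `distortion`: a function of one vector argument with a
#'   parameter list attached.
#' @name distortions
NULL

new_distortion <- function(fun, family, pars) {
  structure(fun, family = family, pars = pars, class = "distortion")
}

#' @rdname distortions
#' @export
distort_affine <- function(a = 1, b = 0) {
  if (a <= 0) stop2("affine distortion needs a positive slope")
  new_distortion(function(x) a * x + b, "affine", list(a = a, b = b))
}

#' @rdname distortions
#' @export
distort_sigmoid <- function(amount, center, width = 0.7) {
  if (width <= 0) stop2("`width` must be positive")
  new_distortion(function(x) x + amount * stats::plogis((x - center) / width),
                 "sigmoid", list(amount = amount, center = center,
                                 width = width))
}

#' @rdname distortions
#' @export
distort_power <- function(gamma, lo = SYNTH_RANGE[1], hi = SYNTH_RANGE[2]) {
  if (gamma <= 0) stop2("`gamma` must be positive")
  new_distortion(function(x) {
    y <- x
    inside <- x >= lo & x <= hi
    y[inside] <- lo + (hi - lo) * ((x[inside] - lo) / (hi - lo))^gamma
    y
  }, "power", list(gamma = gamma, lo = lo, hi = hi))
}

#' @rdname distortions
#' @export
distort_piecewise <- function(breaks_x, breaks_y) {
  if (any(diff(breaks_x) <= 0) || any(diff(breaks_y) <= 0))
    stop2("breakpoints must be strictly increasing")
  new_distortion(function(x)
    stats::approx(breaks_x, breaks_y, xout = x, rule = 2)$y +
      ifelse(x < breaks_x[1], x - breaks_x[1],
             ifelse(x > breaks_x[length(breaks_x)],
                    x - breaks_x[length(breaks_x)], 0)),
    "piecewise", list(breaks_x = breaks_x, breaks_y = breaks_y))
}

# A distortion must be strictly increasing over the generator range.
check_monotone_distortion <- function(f, label = "distortion") {
  g <- seq(SYNTH_RANGE[1] - 0.5, SYNTH_RANGE[2] + 0.5, length.out = 2001)
  if (any(diff(f(g)) <= 0))
    stop2(label, " is not strictly increasing on the data range")
  invisible(TRUE)
}

#' Specify a synthetic multi-batch data set
#'
#' @param pop_means Populations x markers matrix of arcsinh-scale
#'   location parameters (rows optionally named).
#' @param pop_weights Mixture weights, one per population, summing to 1.
#' @param pop_sds Per-marker standard deviation(s); scalar, vector of
#'   length markers, or a matrix like `pop_means` (default 0.35).
#' @param n_batches Number of batches (default 3).
#' @param n_cells_per_sample Cells per aliquot (default 3000).
#' @param aliquots_per_batch Aliquots per batch, the first being the
#'   control and the second the validation sample (default 2).
#' @param batch_effects List of effects, each a list with elements
#'   `batch` (integer), `marker` (name or index), `fun` (a distortion),
#'   and optional `population` (name/index; `NULL` = all populations).
#'   Batch 1 conventionally carries no effect so it can act as a
#'   reference. Control and validation aliquots of a batch share the
#'   batch's distortions.
#' @param control_weights Optional mixture weights used for control
#'   aliquots only (e.g. to withhold a high-expression population from
#'   the controls and reproduce the range-coverage failure mode);
#'   default: same as `pop_weights`.
#' @param seed RNG seed.
#' @return A validated `synthetic_spec`.
#' @export
synthetic_spec <- function(pop_means, pop_weights, pop_sds = 0.35,
                           n_batches = 3, n_cells_per_sample = 3000,
                           aliquots_per_batch = 2, batch_effects = list(),
                           control_weights = NULL, seed = 1) {
  pop_means <- as.matrix(pop_means)
  npop <- nrow(pop_means); nmark <- ncol(pop_means)
  if (is.null(rownames(pop_means)))
    rownames(pop_means) <- paste0("Pop", seq_len(npop))
  if (is.null(colnames(pop_means)))
    colnames(pop_means) <- paste0("Marker", seq_len(nmark))
  if (length(pop_weights) != npop || abs(sum(pop_weights) - 1) > 1e-8)
    stop2("`pop_weights` must have one weight per population and sum to 1")
  if (!is.null(control_weights)) {
    if (length(control_weights) != npop ||
        abs(sum(control_weights) - 1) > 1e-8)
      stop2("`control_weights` must have one weight per population and sum to 1")
  }
  if (length(pop_sds) == 1) pop_sds <- matrix(pop_sds, npop, nmark)
  else if (is.vector(pop_sds) && length(pop_sds) == nmark)
    pop_sds <- matrix(pop_sds, npop, nmark, byrow = TRUE)
  else pop_sds <- as.matrix(pop_sds)
  stopifnot(all(dim(pop_sds) == dim(pop_means)), all(pop_sds > 0))
  if (aliquots_per_batch < 2)
    stop2("need at least 2 aliquots per batch (control + validation)")
  for (e in batch_effects) {
    if (!all(c("batch", "marker", "fun") %in% names(e)))
      stop2("each batch effect needs `batch`, `marker`, `fun`")
    if (!inherits(e$fun, "distortion"))
      stop2("batch-effect `fun` must be built with a distort_*() constructor")
    check_monotone_distortion(e$fun, "batch effect")
  }
  structure(list(pop_means = pop_means, pop_weights = pop_weights,
                 pop_sds = pop_sds, n_batches = as.integer(n_batches),
                 n_cells_per_sample = as.integer(n_cells_per_sample),
                 aliquots_per_batch = as.integer(aliquots_per_batch),
                 batch_effects = batch_effects,
                 control_weights = control_weights, seed = seed),
            class = "synthetic_spec")
}

# Truncated normal draws on SYNTH_RANGE via the probability-integral
# transform.
rtruncnorm <- function(n, mean, sd) {
  plo <- stats::pnorm(SYNTH_RANGE[1], mean, sd)
  phi <- stats::pnorm(SYNTH_RANGE[2], mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic multi-batch data set
#'
#' Draws every aliquot of every batch from the spec's population mixture
#' on the arcsinh scale, applies the batch's distortions (shared by the
#' control and validation aliquot of a batch — the premise that all
#' samples of one batch underwent similar shifts), and returns the
#' samples with ground-truth labels and distortion functions.
#' Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Optional directory; when given, each sample is written
#'   as an FCS file (inverse arcsinh, cofactor 5), per-cell population
#'   labels as `<sample>_labels.csv`, plus a `manifest.json` with the
#'   ground-truth distortion parameters.
#' @return A `synthetic_dataset`: `samples` (list with `data`
#'   (`expr_matrix`, arcsinh scale), `batch`, `role`, `labels`),
#'   `files` (a [batch_labeled_files()] table when `out_dir` is used),
#'   and the `spec`.
#' @export
generate_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  npop <- nrow(spec$pop_means)
  nmark <- ncol(spec$pop_means)
  markers <- colnames(spec$pop_means)
  channels <- paste0("Ch", seq_len(nmark))
  pops <- rownames(spec$pop_means)
  samples <- list()
  si <- 0
  for (b in seq_len(spec$n_batches)) {
    effects <- Filter(function(e) e$batch == b, spec$batch_effects)
    for (a in seq_len(spec$aliquots_per_batch)) {
      si <- si + 1
      role <- if (a == 1) "control" else "validation"
      w <- if (role == "control" && !is.null(spec$control_weights))
        spec$control_weights else spec$pop_weights
      smp <- with_seed(derive_seed(spec$seed, 1000 * b + a), {
        pop_idx <- sample.int(npop, spec$n_cells_per_sample,
                              replace = TRUE, prob = w)
        vals <- matrix(0, spec$n_cells_per_sample, nmark,
                       dimnames = list(NULL, channels))
        for (p in seq_len(npop)) {
          rows <- which(pop_idx == p)
          if (!length(rows)) next
          for (m in seq_len(nmark)) {
            vals[rows, m] <- rtruncnorm(length(rows),
                                        spec$pop_means[p, m],
                                        spec$pop_sds[p, m])
          }
        }
        list(pop_idx = pop_idx, vals = vals)
      })
      vals <- smp$vals
      for (e in effects) {
        m <- if (is.character(e$marker)) match(e$marker, markers)
             else as.integer(e$marker)
        if (is.na(m)) stop2("batch effect names unknown marker: ", e$marker)
        rows <- if (is.null(e$population)) seq_len(nrow(vals))
                else which(pops[smp$pop_idx] == (
                  if (is.character(e$population)) e$population
                  else pops[as.integer(e$population)]))
        vals[rows, m] <- e$fun(vals[rows, m])
      }
      em <- expr_matrix(vals, channels, markers,
                        transform_state = "arcsinh",
                        source_file = sprintf("synthetic:batch%d_%s", b, role))
      samples[[si]] <- list(data = em, batch = paste0("batch", b),
                            role = role, labels = pops[smp$pop_idx])
    }
  }
  names(samples) <- make.unique(vapply(samples, function(s)
    paste0(s$batch, "_", s$role), character(1)), sep = "_")

  files <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    tspec <- transform_spec(5)
    paths <- character(length(samples))
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      path <- file.path(out_dir, paste0(names(samples)[i], ".fcs"))
      write_fcs(invert_transform(s$data, tspec), path)
      utils::write.csv(
        data.frame(cell = seq_along(s$labels), population = s$labels),
        file.path(out_dir, paste0(names(samples)[i], "_labels.csv")),
        row.names = FALSE)
      paths[i] <- path
    }
    manifest <- list(
      seed = spec$seed,
      populations = pops,
      markers = markers,
      weights = spec$pop_weights,
      control_weights = spec$control_weights,
      batch_effects = lapply(spec$batch_effects, function(e)
        list(batch = e$batch, marker = e$marker,
             population = e$population %||% "all",
             family = attr(e$fun, "family"), pars = attr(e$fun, "pars"))))
    jsonlite::write_json(manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- batch_labeled_files(paths,
                                 vapply(samples, `[[`, "", "batch"),
                                 vapply(samples, `[[`, "", "role"))
  }
  structure(list(samples = samples, files = files, spec = spec),
            class = "synthetic_dataset")
}

# Convenience accessors used throughout tests and the evaluation.
dataset_mats <- function(ds, role) {
  sel <- Filter(function(s) s$role == role, ds$samples)
  out <- lapply(sel, `[[`, "data")
  names(out) <- vapply(sel, `[[`, "", "batch")
  out
}
dataset_labels <- function(ds, role) {
  sel <- Filter(function(s) s$role == role, ds$samples)
  out <- lapply(sel, `[[`, "labels")
  names(out) <- vapply(sel, `[[`, "", "batch")
  out
}

#' Control / validation views of a synthetic data set
#'
#' @param ds A [generate_dataset()] result.
#' @return `synthetic_controls` / `synthetic_validation`: named list
#'   (batch -> `expr_matrix`); `synthetic_validation_labels`: named list
#'   of per-cell population labels.
#' @export
synthetic_controls <- function(ds) dataset_mats(ds, "control")

#' @rdname synthetic_controls
#' @export
synthetic_validation <- function(ds) dataset_mats(ds, "validation")

#' @rdname synthetic_controls
#' @export
synthetic_validation_labels <- function(ds) dataset_labels(ds, "validation")

#' Built-in synthetic study designs
#'
#' Named presets emulating the canonical batch-effect structures, all
#' small enough (48,000 cells each: 3 batches x 2 aliquots x 8,000
#' cells, 4 populations, 4 markers) that the full test suite runs in
#' minutes, while keeping the median of the smallest population (10
#' percent of cells) estimable to about 0.015 on the arcsinh scale:
#' * `flat` — identical distributions in every batch; a trained model
#'   should be close to the identity.
#' * `global_shift` — batch-wide opposite affine shifts of Marker1 in
#'   batches 2 and 3.
#' * `cluster_specific` — the same marker shifted in opposite directions
#'   in two different populations, which no single global transformation
#'   can undo.
#' * `nonlinear` — an expression-level-dependent sigmoid shift: the
#'   positive peak of Marker1 moves between batches while the negative
#'   peak stays put, so a linear (two-quantile) map cannot fit both.
#' * `range_gap` — the control aliquots lack the high-expression
#'   population carried by the validation aliquots, and the batch
#'   distortion differs between the low and the high range; models
#'   trained on such range-deficient controls extrapolate wrongly.
#'
#' @param seed Seed stored in every preset (default 1).
#' @return Named list of [synthetic_spec()] objects.
#' @export
make_default_specs <- function(seed = 1) {
  means <- rbind(Pop1 = c(1, 3, 1, 2),
                 Pop2 = c(5, 1, 2, 4),
                 Pop3 = c(2, 6, 5, 1),
                 Pop4 = c(6, 2, 7, 5))
  colnames(means) <- paste0("Marker", 1:4)
  w <- c(0.4, 0.3, 0.2, 0.1)

  n_per <- 8000L

  specs <- list()
  specs$flat <- synthetic_spec(means, w, seed = seed,
                               n_cells_per_sample = n_per)

  specs$global_shift <- synthetic_spec(
    means, w, seed = seed, n_cells_per_sample = n_per,
    batch_effects = list(
      list(batch = 2, marker = "Marker1", fun = distort_affine(1, 0.5)),
      list(batch = 3, marker = "Marker1", fun = distort_affine(1, -0.5))))

  specs$cluster_specific <- synthetic_spec(
    means, w, seed = seed, n_cells_per_sample = n_per,
    batch_effects = list(
      list(batch = 2, marker = "Marker1", population = "Pop1",
           fun = distort_affine(1, 0.6)),
      list(batch = 2, marker = "Marker1", population = "Pop2",
           fun = distort_affine(1, -0.6)),
      list(batch = 3, marker = "Marker1", population = "Pop1",
           fun = distort_affine(1, -0.6)),
      list(batch = 3, marker = "Marker1", population = "Pop2",
           fun = distort_affine(1, 0.6))))

  specs$nonlinear <- synthetic_spec(
    means, w, seed = seed, n_cells_per_sample = n_per,
    batch_effects = list(
      list(batch = 2, marker = "Marker1",
           fun = distort_sigmoid(0.6, center = 3, width = 0.7)),
      list(batch = 3, marker = "Marker1",
           fun = distort_sigmoid(-0.6, center = 3, width = 0.7))))

  # Low/high-range-dependent distortion + a high Marker1 population
  # (Pop4) absent from the controls: the extrapolation hazard.
  gap_means <- means
  gap_means["Pop2", 1] <- 2.5
  gap_means["Pop3", 1] <- 1.8
  gap_w <- c(0.35, 0.25, 0.20, 0.20)
  ctrl_w <- c(0.35, 0.25, 0.20, 0) / 0.80
  gap_effect <- function(a, h)
    new_distortion(function(x) {
      s <- stats::plogis((x - 4) / 0.7)
      x + a * (1 - s) + h * s
    }, "low_high_shift", list(low = a, high = h, center = 4, width = 0.7))
  specs$range_gap <- synthetic_spec(
    gap_means, gap_w, seed = seed, n_cells_per_sample = n_per,
    control_weights = ctrl_w,
    batch_effects = list(
      list(batch = 2, marker = "Marker1", fun = gap_effect(0.7, -0.15)),
      list(batch = 3, marker = "Marker1", fun = gap_effect(-0.7, 0.15))))
  specs
}
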