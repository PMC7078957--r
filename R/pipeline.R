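# Pipeline orchestration: learn a normalization model from per-batch
# control samples (cluster -> quantiles -> goal -> splines) and apply it
# to the other samples of each batch.

#' Batch-labeled file table
#'
#' @param file Character vector of FCS paths.
#' @param batch Batch id per file.
#' @param role One of `"control"`, `"target"`, `"validation"` per file.
#' @return A validated data.frame with columns file, batch, role.
#' @export
batch_labeled_files <- function(file, batch, role) {
  role <- as.character(role)
  ok <- role %in% c("control", "target", "validation")
  if (!all(ok)) stop2("unknown role(s): ", paste(unique(role[!ok]), collapse = ", "))
  df <- data.frame(file = as.character(file), batch = as.character(batch),
                   role = role, stringsAsFactors = FALSE)
  tb <- unique(df$batch[df$role != "control"])
  missing <- setdiff(tb, df$batch[df$role == "control"])
  if (length(missing))
    stop2("batch(es) without a control entry: ", paste(missing, collapse = ", "))
  df
}

#' Normalization parameters
#'
#' All tunable parameters of the pipeline in one declarative object; a
#' copy is stored inside the trained model for provenance.
#'
#' @param clustering_markers Markers used for SOM clustering (`NULL` =
#'   all channels of the controls).
#' @param normalize_markers Markers to normalize (`NULL` = clustering
#'   markers).
#' @param cofactor Arcsinh cofactor (default 5).
#' @param xdim,ydim SOM grid (default 10 x 10).
#' @param k Number of metaclusters (default 25).
#' @param n_quantiles Quantiles per distribution (default 101: 0 to 1 in
#'   steps of 0.01).
#' @param goal `"mean"` for the across-batch mean of control quantiles,
#'   or a batch id to use that batch's quantiles as the goal.
#' @param method `"spline"` (monotone Hermite through all quantiles) or
#'   `"two_quantile"` (affine map through two quantiles).
#' @param clustering `FALSE` forces k = 1 (plain quantile normalization
#'   without clustering).
#' @param two_quantile_probs Probabilities for `method = "two_quantile"`
#'   (default `c(0.001, 0.999)`; use `c(0, 1)` for min-max).
#' @param anchors Spline anchor positions (default `c(0, 8)`).
#' @param min_cells Minimum cells per (batch, cluster) to fit a
#'   transformation; below this the identity is used (default 50).
#' @param total_cells SOM training subsample size (default 1e6).
#' @param epochs,som_alpha SOM schedule, see [train_som()].
#' @param n_resamples,subsample_frac Consensus metaclustering, see
#'   [metacluster()].
#' @param scale_markers Z-scale markers before SOM (default FALSE).
#' @param cv_threshold CV alarm threshold (default 2).
#' @param strict Error (rather than warn) when the CV check flags the
#'   clustering (default FALSE).
#' @param seed Master RNG seed for the whole pipeline.
#' @return A `norm_params` list.
#' @export
norm_params <- function(clustering_markers = NULL, normalize_markers = NULL,
                        cofactor = 5, xdim = 10, ydim = 10, k = 25,
                        n_quantiles = 101, goal = "mean",
                        method = c("spline", "two_quantile"),
                        clustering = TRUE,
                        two_quantile_probs = c(0.001, 0.999),
                        anchors = c(0, 8), min_cells = 50,
                        total_cells = 1e6, epochs = 10,
                        som_alpha = c(0.05, 0.01),
                        n_resamples = 100, subsample_frac = 0.9,
                        scale_markers = FALSE, cv_threshold = 2,
                        strict = FALSE, seed = 1) {
  method <- match.arg(method)
  p <- as.list(environment())
  class(p) <- "norm_params"
  p
}

#' Train a normalization model on per-batch control samples
#'
#' Executes the learning half of the pipeline: aggregate a subsample of
#' all control cells, train the SOM, group nodes into metaclusters, run
#' the cluster-frequency CV stability check, assign every control cell,
#' compute the per-(batch, cluster, marker) quantile distributions, build
#' the goal distribution, and fit one monotone transformation per (batch,
#' cluster, marker).
#'
#' @param controls Either a named list (batch id -> `expr_matrix`, raw or
#'   arcsinh scale; several control files of one batch should be
#'   concatenated with the same batch id), or a [batch_labeled_files()]
#'   data.frame whose control rows are read from disk (multiple control
#'   files per batch are concatenated).
#' @param params A [norm_params()] object.
#' @return A `normalization_model`.
#' @export
train_model <- function(controls, params = norm_params()) {
  stopifnot(inherits(params, "norm_params"))
  if (is.data.frame(controls)) {
    ctl <- controls[controls$role == "control", , drop = FALSE]
    mats <- lapply(split(ctl$file, ctl$batch), function(paths)
      rbind_expr(lapply(paths, read_fcs)))
  } else {
    mats <- controls
  }
  if (is.null(names(mats)) || any(!nzchar(names(mats))))
    stop2("`controls` must be named by batch id")
  if (length(mats) < 2)
    stop2("need control samples from at least 2 batches to align anything")

  cl_markers <- params$clustering_markers %||% mats[[1]]$channel_ids
  nm_markers <- params$normalize_markers %||% cl_markers
  tchannels <- if (is.null(params$clustering_markers) &&
                   is.null(params$normalize_markers)) NULL
               else union(cl_markers, nm_markers)
  tspec <- transform_spec(params$cofactor, tchannels)
  mats <- lapply(mats, function(m)
    if (m$transform_state == "raw") apply_transform(m, tspec) else m)
  k <- if (params$clustering) params$k else 1L

  agg <- aggregate_subsample(mats, total_cells = params$total_cells,
                             seed = derive_seed(params$seed, 1))
  grid <- train_som(agg, markers = cl_markers, xdim = params$xdim,
                    ydim = params$ydim, epochs = params$epochs,
                    alpha = params$som_alpha, scale = params$scale_markers,
                    seed = derive_seed(params$seed, 2))
  meta <- metacluster(grid, k = k, n_resamples = params$n_resamples,
                      subsample_frac = params$subsample_frac,
                      seed = derive_seed(params$seed, 3))

  cv <- compute_cluster_cv(mats, grid, meta, threshold = params$cv_threshold)
  if (cv$flagged) {
    msg <- paste0("cluster-frequency CV check failed (max CV = ",
                  signif(cv$max_cv, 3), " > ", params$cv_threshold,
                  "): some clusters look batch-driven; clustering is ",
                  "inappropriate here - consider k = 1")
    if (params$strict) stop2(msg) else warning(msg)
  }

  clusters <- lapply(mats, function(m) assign_cells(grid, meta, m))
  values <- lapply(mats, function(m) {
    v <- m$values[, match_channels(m, nm_markers), drop = FALSE]
    colnames(v) <- nm_markers
    v
  })
  probs <- quantile_grid(params$n_quantiles)
  qtab <- quantile_table(values, clusters, k = k, markers = nm_markers,
                         probs = probs, min_cells = params$min_cells)
  goal_mode <- if (identical(params$goal, "mean")) "mean" else "batch"
  goal <- build_goal(qtab, mode = goal_mode,
                     batch_id = if (goal_mode == "batch") params$goal)

  batches <- names(mats)
  splines <- lapply(batches, function(b) {
    lapply(seq_len(k), function(j) {
      out <- lapply(nm_markers, function(m) {
        xq <- qtab[b, j, m, ]
        yq <- goal[j, m, ]
        if (anyNA(xq) || anyNA(yq)) return(identity_spline())
        if (params$method == "two_quantile") {
          tp <- params$two_quantile_probs
          xi <- stats::approx(probs, xq, xout = tp, rule = 2)$y
          yi <- stats::approx(probs, yq, xout = tp, rule = 2)$y
          suppressWarnings(fit_linear_two_quantile(xi, yi))
        } else {
          fit_monotone_spline(xq, yq, anchors = params$anchors)
        }
      })
      names(out) <- nm_markers
      out
    })
  })
  names(splines) <- batches

  structure(list(transform = tspec, grid = grid, meta = meta,
                 cv_report = cv, quantiles = qtab, goal = goal,
                 splines = splines, batches = batches,
                 clustering_markers = cl_markers,
                 normalize_markers = nm_markers, k = k,
                 params = params),
            class = "normalization_model")
}

#' @export
print.normalization_model <- function(x, ...) {
  cat("<normalization_model> ", length(x$batches), " batches (",
      paste(x$batches, collapse = ", "), "), ", x$k, " metacluster(s), ",
      length(x$normalize_markers), " markers, method = ",
      x$params$method, "\n", sep = "")
  cat("  SOM ", x$grid$xdim, "x", x$grid$ydim, ", goal = ",
      if (identical(x$params$goal, "mean")) "mean of batches"
      else paste0("batch ", x$params$goal),
      ", max cluster CV = ", signif(x$cv_report$max_cv, 3), "\n", sep = "")
  invisible(x)
}

#' Normalize one sample with a trained model
#'
#' Assigns every cell to a metacluster using the model's clustering, then
#' replaces each value of each normalized marker by the value of the
#' (batch, cluster, marker) transformation. Non-normalized channels and
#' the cell order are untouched; the result stays on the arcsinh scale
#' (invert and write FCS with [normalize_batch()] or manually).
#'
#' @param x `expr_matrix` (raw or arcsinh; raw input is transformed with
#'   the model's transform spec).
#' @param batch_id The batch the sample belongs to; must have been seen
#'   at training.
#' @param model A [train_model()] result.
#' @return The normalized `expr_matrix` (arcsinh scale), with a
#'   `clusters` attribute holding the per-cell metacluster assignment.
#' @export
normalize_sample <- function(x, batch_id, model) {
  stopifnot(inherits(x, "expr_matrix"),
            inherits(model, "normalization_model"))
  if (!batch_id %in% model$batches)
    stop2("unknown batch '", batch_id, "'; model knows: ",
          paste(model$batches, collapse = ", "))
  if (x$transform_state == "raw") x <- apply_transform(x, model$transform)
  cl <- assign_cells(model$grid, model$meta, x)
  cols <- match_channels(x, model$normalize_markers)
  spl_b <- model$splines[[batch_id]]
  for (j in seq_len(model$k)) {
    idx <- which(cl == j)
    if (!length(idx)) next
    for (m in seq_along(model$normalize_markers)) {
      s <- spl_b[[j]][[model$normalize_markers[m]]]
      x$values[idx, cols[m]] <- eval_spline(s, x$values[idx, cols[m]])
    }
  }
  attr(x, "clusters") <- cl
  x
}

#' Normalize a set of files and write new FCS files
#'
#' For every target/validation row of `files`: read, transform, normalize
#' with the row's batch model, invert the transform and write an FCS file
#' named `<prefix><basename>` into `out_dir`. Failures on individual
#' files are logged and do not stop the rest.
#'
#' @param files A [batch_labeled_files()] data.frame.
#' @param model A `normalization_model`.
#' @param out_dir Output directory (created if needed).
#' @param prefix Output filename prefix (default `"Norm_"`).
#' @param roles Roles to process (default target + validation).
#' @return Invisibly, a data.frame log with columns file, output, batch,
#'   n_cells, ok, message.
#' @export
normalize_batch <- function(files, model, out_dir, prefix = "Norm_",
                            roles = c("target", "validation")) {
  stopifnot(is.data.frame(files))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  todo <- files[files$role %in% roles, , drop = FALSE]
  log <- lapply(seq_len(nrow(todo)), function(i) {
    f <- todo$file[i]; b <- todo$batch[i]
    out <- file.path(out_dir, paste0(prefix, basename(f)))
    res <- tryCatch({
      m <- read_fcs(f)
      norm <- normalize_sample(m, b, model)
      raw <- invert_transform(norm, model$transform)
      write_fcs(raw, out)
      data.frame(file = f, output = out, batch = b, n_cells = n_cells(m),
                 ok = TRUE, message = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("normalization failed for ", f, ": ", conditionMessage(e))
      data.frame(file = f, output = NA_character_, batch = b,
                 n_cells = NA_integer_, ok = FALSE,
                 message = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  invisible(do.call(rbind, log))
}

#' Save / load a normalization model
#'
#' The archive is a single R serialization (version 3) holding the grid,
#' metaclustering, goal table, every spline at full float precision and
#' the complete parameter set; the round trip is bit-exact.
#'
#' @param model A `normalization_model`.
#' @param path Archive path.
#' @return `save_model`: invisibly, `path`. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "normalization_model"))
  saveRDS(model, path, version = 3, compress = "gzip")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "normalization_model"))
    stop2("file does not contain a normalization model: ", path)
  model
}
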