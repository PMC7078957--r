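# Self-organizing-map clustering with consensus metaclustering: many
# small SOM clusters first, grouped into a modest number of metaclusters,
# plus the cluster-frequency CV stability check used to validate that the
# clustering itself is not driven by batch effects.

#' Aggregate an equal-share subsample across samples
#'
#' Draws approximately `total_cells` cells without replacement, an equal
#' share from each input matrix. Shares are capped at each file's cell
#' count and the remainder redistributed over the larger files, so small
#' files contribute everything they have. Used to build the SOM training
#' set from the per-batch control samples (default one million cells).
#'
#' @param mats List of `expr_matrix` objects sharing a channel layout.
#' @param total_cells Total cells to draw (default 1e6).
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return An `expr_matrix` with an `origin` attribute giving the source
#'   matrix index of every row.
#' @export
aggregate_subsample <- function(mats, total_cells = 1e6, seed = NULL) {
  stopifnot(length(mats) >= 1)
  sizes <- vapply(mats, n_cells, integer(1))
  if (total_cells < length(mats))
    stop2("`total_cells` must be at least the number of samples")
  take <- subsample_shares(sizes, total_cells)
  picks <- with_seed(seed, lapply(seq_along(mats), function(i) {
    sort(sample.int(sizes[i], take[i]))
  }))
  parts <- lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    m$values <- m$values[picks[[i]], , drop = FALSE]
    m
  })
  out <- rbind_expr(parts)
  attr(out, "origin") <- rep(seq_along(mats), take)
  out
}

# Cap-and-redistribute allocation: equal shares, files smaller than their
# share give everything, freed budget is re-split among the rest.
subsample_shares <- function(sizes, total) {
  n <- length(sizes)
  take <- integer(n)
  remaining <- min(total, sum(sizes))
  open <- rep(TRUE, n)
  repeat {
    quota <- remaining / sum(open)
    capped <- open & (sizes <= quota)
    if (!any(capped)) break
    take[capped] <- sizes[capped]
    remaining <- remaining - sum(sizes[capped])
    open <- open & !capped
    if (!any(open)) return(take)
  }
  base <- floor(remaining / sum(open))
  extra <- remaining - base * sum(open)
  take[open] <- base
  take[which(open)[seq_len(extra)]] <- base + 1L
  take
}

#' Train a self-organizing map
#'
#' Standard online SOM on a rectangular grid: Euclidean distance in marker
#' space, bubble neighbourhood, with learning rate and neighbourhood
#' radius decaying linearly over `epochs` passes through the data. The
#' codebook is initialized from a seeded random sample of data rows.
#'
#' @param data `expr_matrix` on the arcsinh scale.
#' @param markers Markers used for clustering (default: all channels).
#' @param xdim,ydim Grid dimensions (default 10 x 10).
#' @param epochs Passes over the data (default 10).
#' @param alpha Learning-rate schedule `c(start, end)`.
#' @param radius Neighbourhood-radius schedule; default half the grid
#'   diagonal decaying to 1. The bubble cutoff is strict, so the final
#'   phase updates only the best-matching unit.
#' @param scale Z-scale markers before training (default FALSE: arcsinh
#'   values are already on comparable ranges).
#' @param seed RNG seed; training is deterministic given the seed.
#' @return A `som_grid` with the trained codebook.
#' @export
train_som <- function(data, markers = NULL, xdim = 10, ydim = 10,
                      epochs = 10, alpha = c(0.05, 0.01), radius = NULL,
                      scale = FALSE, seed = NULL) {
  stopifnot(inherits(data, "expr_matrix"))
  if (data$transform_state != "arcsinh")
    stop2("SOM training expects arcsinh-transformed data")
  markers <- markers %||% data$channel_ids
  cols <- match_channels(data, markers)
  x <- data$values[, cols, drop = FALSE]
  n_nodes <- as.integer(xdim * ydim)
  if (n_nodes < 1 || xdim < 1 || ydim < 1)
    stop2("grid dimensions must be positive")
  if (nrow(x) < n_nodes)
    stop2("fewer cells (", nrow(x), ") than SOM nodes (", n_nodes, ")")
  if (!all(is.finite(x))) stop2("training data contains non-finite values")

  center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (scale) {
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scl, "/")
  }
  grid <- expand.grid(gx = seq_len(xdim), gy = seq_len(ydim))
  radius <- radius %||% c(sqrt((xdim - 1)^2 + (ydim - 1)^2) / 2, 1)
  if (length(radius) == 1) radius <- c(radius, 1)

  res <- with_seed(seed, {
    init <- x[sample.int(nrow(x), n_nodes), , drop = FALSE]
    ord <- as.vector(vapply(seq_len(epochs),
                            function(e) sample.int(nrow(x)) - 1L,
                            integer(nrow(x))))
    som_train_cpp(x, init, grid$gx, grid$gy, ord,
                  alpha[1], alpha[2], radius[1], radius[2])
  })
  colnames(res) <- markers
  structure(list(xdim = as.integer(xdim), ydim = as.integer(ydim),
                 codebook = res, clustering_markers = markers,
                 scale_center = center, scale_sd = scl, scaled = scale,
                 seed = seed),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat("<som_grid> ", x$xdim, "x", x$ydim, " nodes, ",
      length(x$clustering_markers), " markers\n", sep = "")
  invisible(x)
}

#' Group SOM nodes into metaclusters by consensus hierarchical clustering
#'
#' Resamples subsets of SOM nodes, clusters each subset hierarchically
#' (average linkage, Euclidean distance) into `k` groups, accumulates a
#' co-clustering consensus matrix, and derives the final labels from
#' average-linkage clustering of `1 - consensus` cut at `k`.
#'
#' @param grid A trained [train_som()] result.
#' @param k Number of metaclusters, `2 <= k <=` number of nodes.
#' @param n_resamples Number of resampling rounds (default 100).
#' @param subsample_frac Fraction of nodes per round (default 0.9).
#' @param seed RNG seed.
#' @return A `metaclustering`: integer vector `node_to_meta` (length
#'   nodes, values in 1..k) plus `k`.
#' @export
metacluster <- function(grid, k, n_resamples = 100, subsample_frac = 0.9,
                        seed = NULL) {
  stopifnot(inherits(grid, "som_grid"))
  n <- nrow(grid$codebook)
  if (k < 1 || k > n)
    stop2("`k` must be between 1 and the number of SOM nodes (", n, ")")
  if (k == 1) {
    return(structure(list(node_to_meta = rep(1L, n), k = 1L),
                     class = "metaclustering"))
  }
  if (k == n) {
    return(structure(list(node_to_meta = seq_len(n), k = as.integer(n)),
                     class = "metaclustering"))
  }
  co <- matrix(0, n, n)   # co-clustered counts
  tog <- matrix(0, n, n)  # co-sampled counts
  m <- max(k, ceiling(subsample_frac * n))
  with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      idx <- sort(sample.int(n, m))
      hc <- stats::hclust(stats::dist(grid$codebook[idx, , drop = FALSE]),
                          method = "average")
      lab <- stats::cutree(hc, k = k)
      tog[idx, idx] <- tog[idx, idx] + 1
      for (g in seq_len(k)) {
        mem <- idx[lab == g]
        co[mem, mem] <- co[mem, mem] + 1
      }
    }
  })
  cons <- ifelse(tog > 0, co / tog, 0)
  diag(cons) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  labels <- stats::cutree(hc, k = k)
  structure(list(node_to_meta = as.integer(labels), k = as.integer(k)),
            class = "metaclustering")
}

#' Assign cells to metaclusters
#'
#' Maps each cell to its best-matching SOM node (minimum Euclidean
#' distance over the clustering markers; ties broken by the lowest node
#' index) and returns the node's metacluster label.
#'
#' @param grid A `som_grid`.
#' @param meta A `metaclustering`; `NULL` returns raw node indices.
#' @param cells `expr_matrix` on the arcsinh scale containing all
#'   clustering markers.
#' @return Integer vector of metacluster ids (or node ids), one per cell.
#' @export
assign_cells <- function(grid, meta, cells) {
  stopifnot(inherits(grid, "som_grid"), inherits(cells, "expr_matrix"))
  if (cells$transform_state != "arcsinh")
    stop2("cell assignment expects arcsinh-transformed data")
  cols <- match_channels(cells, grid$clustering_markers)
  x <- cells$values[, cols, drop = FALSE]
  if (grid$scaled)
    x <- sweep(sweep(x, 2, grid$scale_center), 2, grid$scale_sd, "/")
  nodes <- bmu_cpp(x, grid$codebook)
  if (is.null(meta)) return(nodes)
  stopifnot(inherits(meta, "metaclustering"))
  meta$node_to_meta[nodes]
}

#' Cluster-frequency coefficient of variation across control samples
#'
#' The stability check for the clustering step: the fraction of cells per
#' metacluster is computed for every control sample, and for each
#' metacluster the coefficient of variation (sample sd / mean) of those
#' fractions across samples. Large CVs mean some clusters are themselves
#' batch-driven, which makes clustering inappropriate as a preprocessing
#' step before quantile normalization; the conventional alarm threshold
#' is 2.
#'
#' @param control_mats List (>= 2) of `expr_matrix` control samples.
#' @param grid A `som_grid`.
#' @param meta A `metaclustering`.
#' @param threshold Flagging threshold on the maximum CV (default 2).
#' @return A `cv_report`: `frequencies` (samples x clusters),
#'   `cv_per_cluster` (NA for clusters empty in all samples), `max_cv`,
#'   `threshold`, `flagged`.
#' @export
compute_cluster_cv <- function(control_mats, grid, meta, threshold = 2) {
  stopifnot(length(control_mats) >= 2)
  k <- meta$k
  fr <- vapply(control_mats, function(m) {
    cl <- assign_cells(grid, meta, m)
    tabulate(cl, nbins = k) / length(cl)
  }, numeric(k))
  freq <- if (k == 1) matrix(fr, ncol = 1) else t(fr)
  rownames(freq) <- names(control_mats) %||%
    paste0("sample", seq_along(control_mats))
  colnames(freq) <- seq_len(k)
  cv <- vapply(seq_len(k), function(j) {
    f <- freq[, j]
    mu <- mean(f)
    if (mu == 0) NA_real_ else stats::sd(f) / mu
  }, numeric(1))
  max_cv <- if (all(is.na(cv))) NA_real_ else max(cv, na.rm = TRUE)
  structure(list(frequencies = freq, cv_per_cluster = cv, max_cv = max_cv,
                 threshold = threshold,
                 flagged = isTRUE(max_cv > threshold)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", nrow(x$frequencies), " samples x ",
      ncol(x$frequencies), " clusters; max CV = ",
      signif(x$max_cv, 4), if (x$flagged) "  ** FLAGGED **" else "",
      "\n", sep = "")
  invisible(x)
}
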