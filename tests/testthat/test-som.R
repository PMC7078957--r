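# SOM training, consensus metaclustering, cell assignment and the
# cluster-frequency CV stability check.

test_that("aggregate subsampling splits the budget with cap-and-redistribute", {
  a <- make_em(1000, 2, seed = 1)
  b <- make_em(1000, 2, seed = 2)
  agg <- aggregate_subsample(list(a, b), total_cells = 100, seed = 1)
  expect_identical(n_cells(agg), 100L)
  expect_identical(as.vector(table(attr(agg, "origin"))), c(50L, 50L))
  # a small file gives everything; the rest of the budget moves over
  small <- make_em(30, 2, seed = 3)
  agg2 <- aggregate_subsample(list(small, b), total_cells = 100, seed = 1)
  expect_identical(as.vector(table(attr(agg2, "origin"))), c(30L, 70L))
  # the same seed reproduces the same draw
  agg3 <- aggregate_subsample(list(small, b), total_cells = 100, seed = 1)
  expect_identical(agg2$values, agg3$values)
  expect_error(aggregate_subsample(list(a, b), total_cells = 1), "at least")
  # mismatched layouts refuse to combine
  odd <- expr_matrix(matrix(0, 5, 2), c("X", "Y"))
  expect_error(aggregate_subsample(list(a, odd), total_cells = 10, seed = 1),
               "channel layout")
})

blob_data <- function(n = 400, means = list(c(0, 0), c(10, 10)), sd = 0.1,
                      seed = 5) {
  set.seed(seed)
  vals <- do.call(rbind, lapply(means, function(m)
    cbind(rnorm(n, m[1], sd), rnorm(n, m[2], sd))))
  expr_matrix(vals[sample.int(nrow(vals)), ], c("M1", "M2"),
              transform_state = "arcsinh")
}

test_that("SOM codebook finds well-separated blobs (k-means oracle)", {
  em <- blob_data()
  grid <- train_som(em, xdim = 2, ydim = 1, seed = 3)
  km <- stats::kmeans(em$values, centers = rbind(c(0, 0), c(10, 10)))
  ord <- order(grid$codebook[, 1])
  centers <- km$centers[order(km$centers[, 1]), ]
  expect_lt(max(abs(grid$codebook[ord, ] - centers)), 0.5)
})

test_that("a 1x1 grid converges near the data mean", {
  set.seed(8)
  em <- expr_matrix(matrix(rnorm(2000, 3, 1), 1000, 2), c("A", "B"),
                    transform_state = "arcsinh")
  # the online update is an exponentially weighted mean with terminal
  # rate 0.01, so a single run wobbles around the mean with sd about
  # sd*sqrt(alpha/2) ~ 0.07; averaging a few seeds isolates the bias
  cb <- Reduce(`+`, lapply(1:4, function(s)
    train_som(em, xdim = 1, ydim = 1, seed = s)$codebook)) / 4
  expect_lt(max(abs(cb - colMeans(em$values))), 0.1)
})

test_that("SOM training enforces its preconditions", {
  em <- blob_data(n = 10)
  expect_error(train_som(em, xdim = 10, ydim = 10, seed = 1), "fewer cells")
  raw <- make_em(200, 2, seed = 1, state = "raw")
  expect_error(train_som(raw, xdim = 2, ydim = 2, seed = 1), "arcsinh")
})

corner_grid <- function() {
  # four nodes: two tight pairs at the ends of a long rectangle
  cb <- rbind(c(0, 0), c(0.2, 0), c(10, 0), c(10.2, 0))
  colnames(cb) <- c("M1", "M2")
  structure(list(xdim = 2L, ydim = 2L, codebook = cb,
                 clustering_markers = c("M1", "M2"),
                 scale_center = c(0, 0), scale_sd = c(1, 1), scaled = FALSE,
                 seed = 1),
            class = "som_grid")
}

test_that("consensus metaclustering groups tight node pairs", {
  grid <- corner_grid()
  meta <- metacluster(grid, k = 2, seed = 4)
  expect_identical(meta$k, 2L)
  expect_identical(meta$node_to_meta[1], meta$node_to_meta[2])
  expect_identical(meta$node_to_meta[3], meta$node_to_meta[4])
  expect_false(meta$node_to_meta[1] == meta$node_to_meta[3])
  # k = number of nodes: every node its own metacluster
  meta_n <- metacluster(grid, k = 4, seed = 4)
  expect_identical(sort(unique(meta_n$node_to_meta)), 1:4)
  expect_error(metacluster(grid, k = 5, seed = 1), "between")
})

test_that("metacluster labels are stable under node permutation (up to relabeling)", {
  grid <- corner_grid()
  meta <- metacluster(grid, k = 2, seed = 9)
  perm <- c(3, 1, 4, 2)
  gperm <- grid
  gperm$codebook <- grid$codebook[perm, ]
  meta_p <- metacluster(gperm, k = 2, seed = 9)
  # the induced partitions must be identical after undoing the permutation
  expect_identical(length(unique(paste(meta$node_to_meta,
                                       meta_p$node_to_meta[order(perm)]))),
                   2L)
})

test_that("cell assignment matches a brute-force nearest-node search", {
  set.seed(10)
  cb <- matrix(runif(36 * 3, 0, 8), 36, 3,
               dimnames = list(NULL, paste0("M", 1:3)))
  grid <- structure(list(xdim = 6L, ydim = 6L, codebook = cb,
                         clustering_markers = paste0("M", 1:3),
                         scale_center = rep(0, 3), scale_sd = rep(1, 3),
                         scaled = FALSE, seed = 1), class = "som_grid")
  meta <- metacluster(grid, k = 5, seed = 2)
  cells <- expr_matrix(matrix(runif(1000 * 3, 0, 8), 1000, 3),
                       paste0("M", 1:3), transform_state = "arcsinh")
  got <- assign_cells(grid, meta, cells)
  brute <- apply(cells$values, 1, function(v) {
    d <- colSums((t(cb) - v)^2)
    meta$node_to_meta[which.min(d)]
  })
  expect_identical(got, as.integer(brute))
  # a cell equal to a codebook vector lands on that node's metacluster
  onnode <- expr_matrix(cb[17, , drop = FALSE], paste0("M", 1:3),
                        transform_state = "arcsinh")
  expect_identical(assign_cells(grid, meta, onnode), meta$node_to_meta[17])
})

test_that("equidistant cells break ties toward the lowest node index", {
  cb <- rbind(c(0, 0), c(2, 0))
  colnames(cb) <- c("M1", "M2")
  grid <- structure(list(xdim = 2L, ydim = 1L, codebook = cb,
                         clustering_markers = c("M1", "M2"),
                         scale_center = c(0, 0), scale_sd = c(1, 1),
                         scaled = FALSE, seed = 1), class = "som_grid")
  cells <- expr_matrix(matrix(c(1, 0), 1, 2), c("M1", "M2"),
                       transform_state = "arcsinh")
  expect_identical(assign_cells(grid, NULL, cells), 1L)
})

test_that("cluster-frequency CV matches hand computation and flags correctly", {
  grid <- corner_grid()
  meta <- metacluster(grid, k = 2, seed = 4)
  lo <- which(meta$node_to_meta == meta$node_to_meta[1])
  mk <- function(n_lo, n_hi, seed) {
    set.seed(seed)
    vals <- rbind(cbind(rnorm(n_lo, 0.1, 0.05), rnorm(n_lo, 0, 0.05)),
                  cbind(rnorm(n_hi, 10.1, 0.05), rnorm(n_hi, 0, 0.05)))
    expr_matrix(vals, c("M1", "M2"), transform_state = "arcsinh")
  }
  # identical frequency vectors: all CVs zero, nothing flagged
  cv0 <- compute_cluster_cv(list(mk(50, 50, 1), mk(50, 50, 2)), grid, meta)
  expect_equal(unname(cv0$cv_per_cluster), c(0, 0))
  expect_false(cv0$flagged)
  # frequencies 1% vs 3%: CV = sd/mean = sqrt(2)/2
  cv1 <- compute_cluster_cv(list(mk(1, 99, 3), mk(3, 97, 4)), grid, meta)
  low_cluster <- meta$node_to_meta[1]
  expect_equal(unname(cv1$cv_per_cluster[low_cluster]), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_identical(formals(compute_cluster_cv)$threshold, 2)
  # a cluster empty in all samples has an undefined CV, never zero
  cv2 <- compute_cluster_cv(list(mk(50, 0, 5), mk(60, 0, 6)), grid, meta)
  hi_cluster <- meta$node_to_meta[3]
  expect_true(is.na(cv2$cv_per_cluster[hi_cluster]))
  expect_false(is.na(cv2$max_cv))
})

test_that("training is deterministic under a fixed seed", {
  em <- blob_data(n = 300, seed = 12)
  g1 <- train_som(em, xdim = 3, ydim = 3, seed = 77)
  g2 <- train_som(em, xdim = 3, ydim = 3, seed = 77)
  expect_identical(g1$codebook, g2$codebook)
  m1 <- metacluster(g1, k = 3, seed = 78)
  m2 <- metacluster(g2, k = 3, seed = 78)
  expect_identical(m1$node_to_meta, m2$node_to_meta)
  g3 <- train_som(em, xdim = 3, ydim = 3, seed = 79)
  expect_false(identical(g1$codebook, g3$codebook))
})

test_that("cluster frequencies recover mixture weights on separated populations", {
  ds <- generate_dataset(make_default_specs(seed = 31)$flat)
  ctl <- synthetic_controls(ds)
  agg <- aggregate_subsample(ctl, total_cells = 6000, seed = 32)
  grid <- train_som(agg, xdim = 6, ydim = 6, seed = 33)
  meta <- metacluster(grid, k = 4, seed = 34)
  cv <- compute_cluster_cv(ctl, grid, meta)
  truth <- sort(c(0.4, 0.3, 0.2, 0.1))
  for (b in seq_along(ctl)) {
    expect_lt(max(abs(sort(unname(cv$frequencies[b, ])) - truth)), 0.02)
  }
  expect_lt(cv$max_cv, 0.2)
})
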