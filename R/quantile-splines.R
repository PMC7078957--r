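# Quantile distributions, goal construction and monotone Hermite splines —
# the mathematical core of the normalization.

#' Quantile probability grid
#'
#' The default grid is 101 probabilities from 0 to 1 in steps of 0.01, so
#' the 0 quantile is the minimum, 0.5 the median and 1 the maximum of the
#' per-cluster, per-marker distribution being captured.
#'
#' @param n Number of probabilities (default 101).
#' @return Numeric vector of sorted probabilities in \[0, 1\].
#' @export
quantile_grid <- function(n = 101) {
  if (n < 2) stop2("quantile grid needs at least 2 probabilities")
  seq(0, 1, length.out = n)
}

#' Empirical quantiles on a probability grid
#'
#' Linear-interpolation empirical quantiles (the common statistical
#' default, `type = 7`): p = 0 gives the minimum, p = 1 the maximum, and
#' intermediate probabilities interpolate adjacent order statistics.
#'
#' @param values Non-empty numeric vector of finite values.
#' @param probs Probability grid, see [quantile_grid()].
#' @return Non-decreasing vector of quantile values, one per probability.
#' @export
compute_quantiles <- function(values, probs = quantile_grid()) {
  if (length(values) == 0)
    stop2("quantiles are undefined for an empty vector")
  if (!all(is.finite(values)))
    stop2("values must be finite")
  unname(stats::quantile(values, probs = probs, type = 7, names = FALSE))
}

# -- monotone Hermite (Fritsch-Carlson) splines --------------------------

# Fritsch-Carlson tangent filter. Tangents start as averaged secant
# slopes; each interval's (alpha, beta) pair is projected back onto the
# circle of radius 3 when it lies outside the monotonicity region. A
# single sequential sweep (as in the classic implementation) is not
# sufficient: fixing interval k rescales the tangent shared with interval
# k-1 and can push that pair back outside its region, which produces
# small non-monotone dips. Projections only ever shrink tangents (any
# pair outside the region is also outside the radius-3 circle), so the
# sweep is iterated to its fixed point, after which every interval
# satisfies the monotonicity condition.
fc_tangents <- function(x, y) {
  n <- length(x)
  if (n == 1) return(0)
  sx <- diff(y) / diff(x)
  m <- if (n == 2) c(sx, sx) else c(sx[1], (sx[-1] + sx[-(n - 1)]) / 2, sx[n - 1])
  for (pass in 1:100) {
    changed <- FALSE
    for (k in seq_len(n - 1)) {
      sk <- sx[k]
      if (sk == 0) {
        if (m[k] != 0 || m[k + 1] != 0) changed <- TRUE
        m[k] <- 0; m[k + 1] <- 0
      } else {
        alpha <- m[k] / sk
        beta <- m[k + 1] / sk
        a2b3 <- 2 * alpha + beta - 3
        ab23 <- alpha + 2 * beta - 3
        if (a2b3 > 0 && ab23 > 0 && alpha * (a2b3 + ab23) < a2b3 * a2b3) {
          tau <- 3 / sqrt(alpha^2 + beta^2)
          if (tau < 1 - 1e-15) {
            m[k] <- tau * alpha * sk
            m[k + 1] <- tau * beta * sk
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  m
}

new_monotone_spline <- function(knots_x, knots_y, tangents,
                                extrapolation = "linear_slope_1",
                                identity = FALSE) {
  structure(list(knots_x = knots_x, knots_y = knots_y, tangents = tangents,
                 extrapolation = extrapolation, identity = identity),
            class = "monotone_spline")
}

#' @export
print.monotone_spline <- function(x, ...) {
  if (x$identity) cat("<monotone_spline> identity\n")
  else cat("<monotone_spline> ", length(x$knots_x), " knots on [",
           signif(min(x$knots_x), 4), ", ", signif(max(x$knots_x), 4),
           "], extrapolation = ", x$extrapolation, "\n", sep = "")
  invisible(x)
}

#' Identity spline
#'
#' The do-nothing transformation, used wherever a cluster/marker
#' combination had too few cells to estimate quantiles.
#' @return A `monotone_spline` that maps every value to itself.
#' @export
identity_spline <- function() {
  new_monotone_spline(c(0, 1), c(0, 1), c(1, 1), identity = TRUE)
}

# Collapse runs of (near-)equal x to a single knot whose y is the run
# mean. Keeps knots_x strictly increasing as the Hermite scheme requires;
# symmetric treatment of x and y is not needed because y is free to tie.
collapse_knots <- function(x, y, tol = 1e-10) {
  grp <- cumsum(c(TRUE, diff(x) > tol))
  if (max(grp) == length(x)) return(list(x = x, y = y))
  list(x = as.vector(tapply(x, grp, mean)),
       y = as.vector(tapply(y, grp, mean)))
}

#' Fit a monotone cubic Hermite spline through quantile pairs
#'
#' Builds the per-cluster, per-marker transformation: the control sample's
#' quantiles are the x-values, the goal distribution's quantiles the
#' y-values, and anchor points — by default (0,0) and (8,8), bracketing
#' the usual arcsinh range — are merged into the knot set to avoid
#' spurious extrapolation. Runs of (near-)duplicate x-knots (frequent when
#' a marker is zero for many cells) are collapsed to a single knot with
#' the mean y. Tangents follow the Fritsch-Carlson scheme, so
#' non-decreasing knots yield a non-decreasing interpolant; the spline
#' passes through every retained knot exactly.
#'
#' @param x_quantiles,y_quantiles Non-decreasing vectors of equal length.
#' @param anchors Numeric vector `c(lo, hi)` of anchor positions merged as
#'   knots `(lo, lo)` and `(hi, hi)`; `NULL` to skip anchoring.
#' @return A `monotone_spline`. With fewer than 2 distinct knots after
#'   collapsing, the identity spline is returned with a warning.
#' @export
fit_monotone_spline <- function(x_quantiles, y_quantiles, anchors = c(0, 8)) {
  if (length(x_quantiles) != length(y_quantiles))
    stop2("x and y quantiles must have the same length")
  if (is.unsorted(x_quantiles) || is.unsorted(y_quantiles))
    stop2("quantile vectors must be non-decreasing")
  x <- as.double(x_quantiles)
  y <- as.double(y_quantiles)
  if (!is.null(anchors)) {
    for (a in anchors) {
      if (a <= min(x) - 1e-10 || a >= max(x) + 1e-10) {
        # anchor outside the data range: clamp its y to keep knots monotone
        ya <- if (a < min(x)) min(a, y[1]) else max(a, y[length(y)])
        x <- c(x, a); y <- c(y, ya)
      }
      # anchors falling inside the data range are dropped: the data
      # already constrains the fit there
    }
    ord <- order(x)
    x <- x[ord]; y <- y[ord]
  }
  ck <- collapse_knots(x, y)
  x <- ck$x; y <- cummax(ck$y)  # guard against float jitter from run means
  if (length(x) < 2) {
    warning("fewer than 2 distinct knots; falling back to identity spline")
    return(identity_spline())
  }
  new_monotone_spline(x, y, fc_tangents(x, y))
}

#' Evaluate a monotone spline
#'
#' Piecewise cubic Hermite evaluation inside the knot range; outside it,
#' linear continuation with slope 1 from the boundary knot (the anchoring
#' intent extended below/above the anchors, since arcsinh values can be
#' slightly negative). The two-quantile linear transformation instead
#' extrapolates with its own line slope.
#'
#' @param s A `monotone_spline`.
#' @param x Numeric vector; all reals accepted.
#' @return Numeric vector of transformed values.
#' @export
eval_spline <- function(s, x) {
  stopifnot(inherits(s, "monotone_spline"))
  if (s$identity) return(as.double(x))
  kx <- s$knots_x; ky <- s$knots_y; m <- s$tangents
  n <- length(kx)
  out <- numeric(length(x))
  lo <- x < kx[1]
  hi <- x > kx[n]
  mid <- !(lo | hi)
  if (any(mid)) {
    xi <- x[mid]
    i <- findInterval(xi, kx, all.inside = TRUE)
    h <- kx[i + 1] - kx[i]
    t <- (xi - kx[i]) / h
    h00 <- (1 + 2 * t) * (1 - t)^2
    h10 <- t * (1 - t)^2
    h01 <- t^2 * (3 - 2 * t)
    h11 <- t^2 * (t - 1)
    out[mid] <- h00 * ky[i] + h10 * h * m[i] + h01 * ky[i + 1] + h11 * h * m[i + 1]
  }
  slope_lo <- if (s$extrapolation == "linear_boundary_slope") m[1] else 1
  slope_hi <- if (s$extrapolation == "linear_boundary_slope") m[n] else 1
  if (any(lo)) out[lo] <- ky[1] + slope_lo * (x[lo] - kx[1])
  if (any(hi)) out[hi] <- ky[n] + slope_hi * (x[hi] - kx[n])
  out
}

#' Two-quantile linear transformation
#'
#' The linear alternative to the spline: the affine map sending a pair of
#' control quantiles (typically the 0.001 and 0.999 quantiles, or min and
#' max) onto the corresponding goal quantiles. No anchor augmentation; the
#' line extends over the whole real axis.
#'
#' @param x_q,y_q Strictly increasing numeric pairs `c(lo, hi)`.
#' @return A `monotone_spline` with 2 knots, linear throughout. A
#'   degenerate x range falls back to the identity with a warning.
#' @export
fit_linear_two_quantile <- function(x_q, y_q) {
  stopifnot(length(x_q) == 2, length(y_q) == 2)
  if (x_q[2] <= x_q[1]) {
    warning("degenerate x-quantile range; falling back to identity")
    return(identity_spline())
  }
  if (y_q[2] < y_q[1]) stop2("y quantiles must be non-decreasing")
  slope <- (y_q[2] - y_q[1]) / (x_q[2] - x_q[1])
  new_monotone_spline(as.double(x_q), as.double(y_q), c(slope, slope),
                      extrapolation = "linear_boundary_slope")
}

# -- quantile tables and goals -------------------------------------------

#' Per-batch, per-cluster, per-marker quantile table
#'
#' Computes the empirical quantile distributions that describe each
#' control sample: for every batch, metacluster and marker, the quantiles
#' of the cluster's cells on that marker. Combinations with fewer than
#' `min_cells` cells are recorded as `NA` (their transformation will be
#' the identity).
#'
#' @param values_by_batch Named list: batch id -> numeric matrix of
#'   arcsinh-scale intensities (cells x markers, columns named).
#' @param clusters_by_batch Named list: batch id -> integer metacluster
#'   assignment per cell (values in 1..k).
#' @param k Number of metaclusters.
#' @param markers Character vector of marker columns to tabulate.
#' @param probs Probability grid.
#' @param min_cells Minimum cells needed to estimate quantiles (default 50).
#' @return A `quantile_table`: 4-d array \[batch, cluster, marker,
#'   probability\] with an `n_cells` attribute (batch x cluster counts).
#' @export
quantile_table <- function(values_by_batch, clusters_by_batch, k, markers,
                           probs = quantile_grid(), min_cells = 50) {
  batches <- names(values_by_batch)
  stopifnot(length(batches) > 0, identical(batches, names(clusters_by_batch)))
  arr <- array(NA_real_,
               dim = c(length(batches), k, length(markers), length(probs)),
               dimnames = list(batch = batches, cluster = seq_len(k),
                               marker = markers, prob = signif(probs, 6)))
  ncells <- matrix(0L, length(batches), k,
                   dimnames = list(batches, seq_len(k)))
  for (b in seq_along(batches)) {
    vals <- values_by_batch[[b]]
    cl <- clusters_by_batch[[b]]
    stopifnot(nrow(vals) == length(cl))
    for (j in seq_len(k)) {
      idx <- which(cl == j)
      ncells[b, j] <- length(idx)
      if (length(idx) >= min_cells) {
        for (m in seq_along(markers)) {
          arr[b, j, m, ] <- compute_quantiles(vals[idx, markers[m]], probs)
        }
      }
    }
  }
  structure(arr, n_cells = ncells, probs = probs, class = "quantile_table")
}

#' Goal quantile distribution
#'
#' The target the per-batch distributions are aligned to: either the
#' arithmetic mean of the control quantiles over batches (the default), or
#' the quantiles of one designated batch. Batches whose quantiles are
#' undefined for a cluster/marker (too few cells) are excluded from the
#' mean for that combination.
#'
#' @param table A [quantile_table()].
#' @param mode `"mean"` or `"batch"`.
#' @param batch_id Required when `mode = "batch"`: the goal batch.
#' @return A `goal_distribution`: 3-d array \[cluster, marker,
#'   probability\]; `NA` where no batch had enough cells.
#' @export
build_goal <- function(table, mode = c("mean", "batch"), batch_id = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "quantile_table"))
  dn <- dimnames(table)
  if (mode == "batch") {
    if (is.null(batch_id) || !batch_id %in% dn$batch)
      stop2("`batch_id` must name a batch in the table: ",
            paste(dn$batch, collapse = ", "))
    goal <- array(table[batch_id, , , ], dim = dim(table)[2:4],
                  dimnames = dn[2:4])
  } else {
    goal <- apply(table, c(2, 3, 4), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  }
  structure(goal, mode = mode, batch_id = batch_id,
            probs = attr(table, "probs"), class = "goal_distribution")
}
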