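# Quantile computation, goal construction and the monotone spline core.

test_that("empirical quantiles follow the interpolated order-statistic definition", {
  expect_equal(compute_quantiles(c(3, 3, 3)), rep(3, 101))
  # arithmetic sequence: the p-quantile of 0..100 is 100*p exactly
  q <- compute_quantiles(0:100, c(0, 0.25, 0.5, 1))
  expect_equal(q, c(0, 25, 50, 100))
  set.seed(5)
  v <- rnorm(333)
  expect_equal(compute_quantiles(v, c(0, 0.5, 1)),
               c(min(v), stats::median(v), max(v)))
  expect_error(compute_quantiles(numeric(0)), "empty")
  # default grid: 101 probabilities from 0 to 1 in steps of 0.01
  expect_equal(quantile_grid(), seq(0, 1, by = 0.01))
})

test_that("goal distribution is the across-batch mean or a designated batch", {
  vb <- list(b1 = matrix(rnorm(600, 5), 200, 3,
                         dimnames = list(NULL, c("m1", "m2", "m3"))))
  vb$b2 <- vb$b1 + 1
  cl <- list(b1 = rep(1L, 200), b2 = rep(1L, 200))
  qt <- quantile_table(vb, cl, k = 1, markers = c("m1", "m2", "m3"),
                       min_cells = 50)
  # quantiles of v and v+1 differ by exactly 1 -> mean goal is v + 0.5
  goal <- build_goal(qt, "mean")
  expect_equal(goal[1, , ], qt["b1", 1, , ] + 0.5, tolerance = 1e-12)
  # fixed-batch goal copies that batch
  goal2 <- build_goal(qt, "batch", batch_id = "b2")
  expect_equal(goal2[1, , ], qt["b2", 1, , ], tolerance = 1e-15)
  expect_error(build_goal(qt, "batch", batch_id = "nope"), "batch")
  # single batch, mean mode -> goal equals that batch
  qt1 <- quantile_table(vb["b1"], cl["b1"], k = 1, markers = "m1")
  expect_equal(build_goal(qt1, "mean")[1, 1, ], qt1["b1", 1, 1, ])
})

test_that("quantile table marks sparse clusters as undefined", {
  vb <- list(b1 = matrix(rnorm(300), 100, 3,
                         dimnames = list(NULL, paste0("m", 1:3))))
  cl <- list(b1 = c(rep(1L, 90), rep(2L, 10)))
  qt <- quantile_table(vb, cl, k = 2, markers = "m1", min_cells = 50)
  expect_false(anyNA(qt["b1", 1, 1, ]))
  expect_true(all(is.na(qt["b1", 2, 1, ])))
  expect_identical(attr(qt, "n_cells")["b1", ], c("1" = 90L, "2" = 10L))
})

test_that("fitting identity data recovers the identity transformation", {
  set.seed(2)
  v <- sort(runif(101, 0.2, 7.5))
  s <- fit_monotone_spline(v, v)
  t <- seq(0, 8, length.out = 2000)
  expect_lt(max(abs(eval_spline(s, t) - t)), 1e-12)
})

test_that("anchors enter the knot set and bound extrapolation at slope 1", {
  x <- seq(1, 4, length.out = 20)
  s <- fit_monotone_spline(x, x + 0.3, anchors = c(0, 8))
  expect_equal(min(s$knots_x), 0)
  expect_equal(max(s$knots_x), 8)
  expect_equal(eval_spline(s, 0), 0)
  expect_equal(eval_spline(s, 8), 8)
  # outside the anchors: linear continuation with slope 1
  expect_equal(eval_spline(s, -1), -1)
  expect_equal(eval_spline(s, 9.5), 9.5)
  s0 <- fit_monotone_spline(c(0, 2), c(0, 3), anchors = NULL)
  expect_equal(eval_spline(s0, -1), -1)   # slope-1 below the (0,0) knot
})

test_that("spline is monotone and interpolates its knots exactly", {
  x <- c(0, 1, 2, 8)
  y <- c(0, 0.5, 2.5, 8)
  s <- fit_monotone_spline(x, y, anchors = NULL)
  t <- seq(0, 8, length.out = 10000)
  expect_true(all(diff(eval_spline(s, t)) >= -1e-12))
  expect_equal(eval_spline(s, x), y, tolerance = 1e-14)
  # property: random monotone knot sets stay monotone on a dense grid
  for (seed in 1:25) {
    k <- random_monotone_knots(sample(4:30, 1), seed = seed)
    s <- fit_monotone_spline(k$x, k$y, anchors = NULL)
    g <- seq(min(k$x), max(k$x), length.out = 3000)
    expect_true(all(diff(eval_spline(s, g)) >= -1e-10))
    expect_equal(eval_spline(s, s$knots_x), s$knots_y, tolerance = 1e-12)
  }
})

test_that("spline agrees with the reference monotone Hermite interpolator", {
  # The reference applies the Fritsch-Carlson filter in a single sweep,
  # which on rare knot sets leaves it slightly non-monotone; our fit
  # iterates the filter to its fixed point. Where the single sweep
  # already suffices (the reference's own output is monotone), the two
  # must agree; where it does not, ours must stay monotone anyway.
  compared <- 0
  for (seed in 1:20) {
    k <- random_monotone_knots(sample(5:40, 1), seed = 100 + seed)
    s <- fit_monotone_spline(k$x, k$y, anchors = NULL)
    ref <- stats::splinefun(k$x, k$y, method = "monoH.FC")
    g <- seq(min(k$x), max(k$x), length.out = 4000)
    if (all(diff(ref(g)) >= 0)) {
      expect_lt(max(abs(eval_spline(s, g) - ref(g))), 1e-8)
      compared <- compared + 1
    } else {
      expect_true(all(diff(eval_spline(s, g)) >= -1e-10))
    }
  }
  expect_gt(compared, 10)  # the comparison must not be vacuous
})

test_that("duplicate x-knots collapse to their mean y and keep knots strict", {
  x <- c(0, 0, 0, 1, 2, 2, 3)
  y <- c(0, 0.1, 0.2, 1, 2, 2.4, 3)
  s <- fit_monotone_spline(x, y, anchors = NULL)
  expect_true(all(diff(s$knots_x) > 0))
  expect_equal(s$knots_x, c(0, 1, 2, 3))
  expect_equal(s$knots_y, c(0.1, 1, 2.2, 3))
  # a constant marker (all duplicates) degrades to the identity with a warning
  expect_warning(s2 <- fit_monotone_spline(rep(1, 5), rep(2, 5),
                                           anchors = NULL),
                 "identity")
  expect_true(s2$identity)
  expect_equal(eval_spline(s2, c(-1, 0, 4)), c(-1, 0, 4))
})

test_that("pull-through: transforming a sample moves its quantiles onto the goal", {
  set.seed(9)
  v <- rnorm(5000, 3, 1)
  probs <- quantile_grid()
  xq <- compute_quantiles(v, probs)
  yq <- compute_quantiles(rnorm(5000, 3.6, 0.8), probs)
  s <- fit_monotone_spline(xq, yq)
  got <- compute_quantiles(eval_spline(s, v), probs)
  expect_lt(stats::median(abs(got - yq)), 1e-3)
})

test_that("two-quantile map is the affine alignment of its quantile pair", {
  s <- fit_linear_two_quantile(c(1, 5), c(0, 8))
  expect_equal(eval_spline(s, 3), 4)        # midpoint maps to midpoint
  expect_equal(eval_spline(s, c(1, 5)), c(0, 8))
  # full-line extrapolation with the line's own slope (2 here)
  expect_equal(eval_spline(s, 7), 12)
  expect_equal(eval_spline(s, 0), -2)
  # identical pairs give the identity map
  s_id <- fit_linear_two_quantile(c(2, 6), c(2, 6))
  expect_equal(eval_spline(s_id, c(0, 3, 9)), c(0, 3, 9))
  expect_warning(s_d <- fit_linear_two_quantile(c(2, 2), c(0, 1)),
                 "degenerate")
  expect_true(s_d$identity)
})
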