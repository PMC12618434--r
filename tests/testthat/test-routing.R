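# Routing functions: construction, critical points, classification,
# genericity.

test_that("degree bookkeeping fixes the denominator exponent", {
  te <- fixtures("two_ellipses")
  rf <- build_routing_function(te, center = c(1.2, 0.7))
  expect_equal(rf$deg_num, 6)   # two conics + two coordinates
  expect_equal(rf$D, 4)         # denominator degree 8
  # single hyperplane {a1 - 1} on the positive line: numerator a1(a1-1)
  h <- hypersurface_arrangement(list("a1 - 1"), "a1", normalized = TRUE)
  rf1 <- build_routing_function(h, seed = 2)
  expect_equal(rf1$deg_num, 2)
  expect_equal(rf1$D, 2)
})

test_that("the competition-colonization routing function has exponent 8", {
  lc <- fixtures("levins_culver")
  arr <- total_boundary(lc)
  rf <- build_routing_function(arr, seed = 1)
  expect_equal(rf$deg_num, 14)
  expect_equal(rf$D, 8)
})

test_that("two-ellipse critical points: 9 in the open positive quadrant", {
  te <- fixtures("two_ellipses")
  rf <- build_routing_function(te, center = c(1.2, 0.7))
  A <- critical_points(rf, method = "resultant")
  expect_equal(nrow(A), 9)
  pts <- lapply(seq_len(nrow(A)), function(i) classify(rf, A[i, ]))
  idx <- vapply(pts, `[[`, 0L, "index")
  expect_equal(sum(idx == 0), 7)
  expect_equal(sum(idx == 1), 2)
  expect_true(genericity_check(rf, pts)$pass)
  # solver independence: multistart finds the same 9 points
  A2 <- critical_points(rf, method = "multistart", box = 16, seed = 3)
  expect_equal(nrow(A2), 9)
  ord <- function(M) M[do.call(order, as.data.frame(M)), ]
  expect_equal(ord(A2), ord(A), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("critical-point sets are invariant across multistart seeds", {
  te <- fixtures("two_ellipses")
  rf <- build_routing_function(te, center = c(1.2, 0.7))
  counts <- vapply(c(11, 29, 57), function(s)
    nrow(critical_points(rf, method = "multistart", box = 16, seed = s)), 0)
  expect_equal(counts, rep(9, 3))
})

test_that("a single positive hyperplane yields two opposite-signed extrema", {
  h <- hypersurface_arrangement(list("a1 - 1"), "a1", normalized = TRUE)
  rf <- build_routing_function(h, seed = 2)
  A <- critical_points(rf)
  expect_equal(nrow(A), 2)
  v <- rf_value(rf, A)
  expect_equal(sum(v > 0), 1)
  expect_equal(sum(v < 0), 1)
  expect_true(any(A > 0 & A < 1) && any(A > 1))
  # 1-D oracle: sign changes of the numerically scanned derivative
  xs <- seq(1e-3, 15, length.out = 40001)
  vals <- rf_value(rf, matrix(xs, ncol = 1))
  dv <- diff(vals)
  flips <- sum(diff(sign(dv[abs(dv) > 1e-18])) != 0)
  expect_equal(flips, 2)
})

test_that("circle-arrangement counts match a dense grid scan", {
  circ <- hypersurface_arrangement(list("(a1-3)^2 + (a2-3)^2 - 1"), c("a1", "a2"),
                                   normalized = TRUE)
  rf <- build_routing_function(circ, center = c(1.3, 0.8))
  A <- critical_points(rf)
  n_scan <- grid_extrema_scan(rf, box = c(0.05, 8), res = 400)
  pts <- lapply(seq_len(nrow(A)), function(i) classify(rf, A[i, ]))
  idx <- vapply(pts, `[[`, 0L, "index")
  expect_equal(sum(idx == 0), n_scan)
})

test_that("a symmetric center fails the genericity check and is redrawn", {
  # two congruent circles mirror-symmetric about a1 = 5, center on the axis
  sym <- hypersurface_arrangement(
    list("(a1-3)^2 + (a2-3)^2 - 1", "(a1-7)^2 + (a2-3)^2 - 1"),
    c("a1", "a2"), normalized = TRUE)
  # full-space mode: the coordinate factors would break the mirror symmetry
  rf <- build_routing_function(sym, center = c(5, 1), restrict_positive = FALSE)
  A <- critical_points(rf)
  pts <- lapply(seq_len(nrow(A)), function(i) classify(rf, A[i, ]))
  chk <- genericity_check(rf, pts)
  expect_false(chk$pass)
  expect_match(paste(chk$reasons, collapse = " "), "duplicate")
  # empty point list passes vacuously
  expect_true(genericity_check(rf, list())$pass)
  # the redraw wrapper recovers with a generic center
  rp <- suppressMessages(routing_points(sym, seed = 1))
  expect_true(genericity_check(rp$rf, rp$points)$pass)
})

test_that("routing functions vanish at infinity below the critical scale", {
  te <- fixtures("two_ellipses")
  rf <- build_routing_function(te, center = c(1.2, 0.7))
  A <- critical_points(rf, method = "resultant")
  vmin <- min(abs(rf_value(rf, A)))
  set.seed(8)
  far <- matrix(runif(200, 0, 1), 100, 2)
  far <- far / sqrt(rowSums(far^2)) * runif(100, 1e3, 1e5)
  expect_lt(max(abs(rf_value(rf, far))), vmin / 10)
})

test_that("degenerate Hessians are flagged", {
  te <- fixtures("two_ellipses")
  rf <- build_routing_function(te, center = c(1.2, 0.7))
  A <- critical_points(rf, method = "resultant")
  p <- classify(rf, A[1, ])
  expect_false(p$degenerate)
  expect_equal(p$index + sum(sign(p$hess_eigenvalues) != sign(p$value)),
               length(p$coords))
  # index-0 extremum: negative-definite Hessian at a positive value
  top <- classify(rf, A[which.max(rf_value(rf, A)), ])
  expect_equal(top$index, 0)
  expect_true(all(top$hess_eigenvalues < 0))
  expect_gt(top$value, 0)
})
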