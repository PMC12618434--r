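# Gradient-flow connectivity: tracing, the routing graph, membership.

two_ellipse_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      te <- fixtures("two_ellipses")
      rf <- build_routing_function(te, center = c(1.2, 0.7))
      A <- critical_points(rf, method = "resultant")
      pts <- lapply(seq_len(nrow(A)), function(i) classify(rf, A[i, ]))
      g <- build_routing_graph(rf, pts)
      cache <<- list(arr = te, rf = rf, pts = pts, graph = g)
    }
    cache
  }
})

test_that("the two-ellipse routing graph has six connected components", {
  pl <- two_ellipse_pipeline()
  expect_length(pl$pts, 9)
  comps <- connected_components(pl$graph)
  expect_length(comps, 6)
  # every component representative is an index-0 point of largest |r|
  for (cm in comps) {
    rep <- pl$graph$vertices[[cm$representative]]
    expect_equal(rep$index, 0)
    vals <- vapply(cm$vertices, function(i) {
      v <- pl$graph$vertices[[i]]
      if (v$index == 0) abs(v$value) else -Inf
    }, 0)
    expect_equal(abs(rep$value), max(vals))
  }
})

test_that("saddle traces ascend to extrema in the same sign-region", {
  pl <- two_ellipse_pipeline()
  sadd <- which(vapply(pl$pts, `[[`, 0L, "index") > 0)
  sig <- function(x) paste(sign(stabscape:::arr_eval(pl$arr, matrix(x, 1))),
                           collapse = ",")
  for (i in sadd) {
    p <- pl$pts[[i]]
    for (sgn in c(1, -1)) {
      land <- trace_unstable_path(pl$rf, p, sgn * p$unstable_dirs[[1]], pl$pts)
      expect_false(is.na(land))
      q <- pl$pts[[land]]
      expect_gte(abs(q$value), abs(p$value))
      # same region: identical sign vector over the arrangement
      expect_equal(sig(q$coords), sig(p$coords))
      pv <- attr(land, "path_values")
      expect_gte(abs(pv[2]), abs(pv[1]))
    }
  }
  # an index-0 point has no unstable directions to trace
  ext <- which(vapply(pl$pts, `[[`, 0L, "index") == 0)[1]
  expect_length(pl$pts[[ext]]$unstable_dirs, 0)
})

test_that("membership queries agree with sign-vector flood fill", {
  pl <- two_ellipse_pipeline()
  # a perturbed routing point locates to its own component
  p1 <- pl$pts[[1]]
  own <- locate(pl$rf, pl$graph, p1$coords + 1e-6)
  expect_equal(as.integer(own), pl$graph$component_id[1])
  set.seed(42)
  P <- matrix(runif(600, 0.2, 9.8), 300, 2)
  V <- stabscape:::arr_eval(pl$arr, P)
  P <- P[apply(abs(V), 1, min) > 0.3, , drop = FALSE][1:150, ]
  loc <- apply(P, 1, function(a) as.integer(locate(pl$rf, pl$graph, a)))
  sig <- apply(sign(stabscape:::arr_eval(pl$arr, P)), 1, paste, collapse = ",")
  # within a located component the sign vector is constant, and distinct
  # sign vectors never share a component
  for (cmp in unique(loc)) expect_length(unique(sig[loc == cmp]), 1)
  # (1,1) region is ambient: both inside-both and outside-both would be
  # (-1,-1)/(1,1); the two lens lobes share signs but not components
  expect_gte(length(unique(loc)), length(unique(sig)))
  # boundary queries are rejected with a distance diagnostic
  bdy <- c(5, 3)  # on the first ellipse
  expect_error(locate(pl$rf, pl$graph, bdy), "boundary")
})

test_that("one-dimensional graphs and empty arrangements behave", {
  h <- hypersurface_arrangement(list("a1 - 1"), "a1", normalized = TRUE)
  rp <- routing_points(h, seed = 2)
  g <- build_routing_graph(rp$rf, rp$points)
  expect_length(connected_components(g), 2)
  # no real points in the domain: empty graph, zero components
  none <- hypersurface_arrangement(list("a1^2 + a2^2 + 1"), c("a1", "a2"),
                                   normalized = TRUE)
  rfn <- build_routing_function(none, seed = 1)
  # the imaginary conic contributes no wall; only coordinate walls remain,
  # so the positive quadrant is one region
  An <- critical_points(rfn, method = "resultant")
  ptsn <- lapply(seq_len(nrow(An)), function(i) classify(rfn, An[i, ]))
  gn <- build_routing_graph(rfn, ptsn)
  expect_length(connected_components(gn), 1)
})

test_that("graph components are invariant across routing centers", {
  te <- fixtures("two_ellipses")
  for (s in c(1, 7, 13)) {
    rp <- suppressMessages(routing_points(te, seed = s, method = "resultant"))
    g <- build_routing_graph(rp$rf, rp$points)
    expect_length(connected_components(g), 6)
  }
})
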