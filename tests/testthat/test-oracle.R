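# Grid and roadmap component-counting oracles; random arrangements.

test_that("grid flood fill counts the two-ellipse regions", {
  te <- fixtures("two_ellipses")
  gl <- grid_components(te, box = c(0, 10), resolution = 400)
  expect_equal(gl$count, 6)
  # representatives are interior: every arrangement polynomial is bounded
  # away from zero there
  V <- stabscape:::arr_eval(te, gl$representatives)
  expect_gt(min(abs(V)), 0.05)
  # stabilization under doubling
  gs <- grid_components(te, box = c(0, 10), resolution = 100, stabilize = TRUE)
  expect_true(gs$stable)
  expect_equal(gs$count, 6)
})

test_that("an empty arrangement is a single region", {
  em <- hypersurface_arrangement(list(), c("a1", "a2"))
  gl <- grid_components(em, box = c(0, 5), resolution = 50)
  expect_equal(gl$count, 1)
})

test_that("roadmap and grid oracles agree on planar fixtures", {
  te <- fixtures("two_ellipses")
  rm <- roadmap_components(te, n = 6000, seed = 1, box = 10)
  expect_false(rm$homogeneous)
  expect_equal(rm$count, 6)
})

test_that("one-dimensional line arrangements count intervals", {
  set.seed(31)
  for (rep in 1:5) {
    roots <- sort(sample(1:12, 3))
    polys <- lapply(roots, function(r)
      stabscape:::parse_poly(paste0("a1 - ", r), "a1"))
    arr <- hypersurface_arrangement(polys, "a1", normalized = TRUE)
    gl <- grid_components(arr, box = c(0, 15), resolution = 600)
    expect_equal(gl$count, length(unique(roots)) + 1)
    rp <- routing_points(arr, seed = rep)
    g <- build_routing_graph(rp$rf, rp$points)
    expect_length(connected_components(g), length(unique(roots)) + 1)
  }
})

test_that("random arrangements are reproducible and non-degenerate", {
  a1 <- random_arrangement(2, 3, seed = 4)
  a2 <- random_arrangement(2, 3, seed = 4)
  expect_equal(vapply(a1$polys, stabscape:::qp_string, ""),
               vapply(a2$polys, stabscape:::qp_string, ""))
  expect_length(a1$polys, 3)
  for (i in seq_along(a1$polys))
    for (j in seq_len(i - 1))
      expect_false(stabscape:::qp_proportional(a1$polys[[i]], a1$polys[[j]]))
  # m = 0: empty arrangement, one region in the positive quadrant
  a0 <- random_arrangement(2, 0, seed = 1)
  gl <- grid_components(a0, box = c(0, 10), resolution = 50)
  expect_equal(gl$count, 1)
})

test_that("routing and grid counts agree on a random conic arrangement", {
  ra <- random_arrangement(2, 2, degree_menu = 2, seed = 7)
  rp <- suppressMessages(routing_points(ra, seed = 7, method = "multistart",
                                        box = 14, grid_assist = TRUE))
  g <- build_routing_graph(rp$rf, rp$points)
  gl <- grid_components(ra, box = c(0, 14), resolution = 140, stabilize = TRUE)
  expect_equal(length(connected_components(g)), gl$count)
})
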