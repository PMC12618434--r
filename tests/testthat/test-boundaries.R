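# Equilibrium-ideal decomposition and boundary elimination.

rat <- stabscape:::rat
parse_poly <- stabscape:::parse_poly
qp_key <- function(p) stabscape:::qp_key(stabscape:::qp_normalize(p))

test_that("the quadratic family's singular boundary is the discriminant", {
  sys <- fixtures("quadratic_discriminant")
  comps <- decompose_equilibrium_ideal(sys)
  expect_length(comps, 1)
  sb <- singular_boundary(comps[[1]], sys)
  expect_length(sb, 1)
  expect_true(stabscape:::qp_proportional(
    sb[[1]], parse_poly("a2^2 - 4*a1*a3", c("a1", "a2", "a3"))))
})

test_that("simple singular boundaries: double root and cubic discriminant", {
  s1 <- ode_system("x", "a1", "x^2 - a1")
  c1 <- decompose_equilibrium_ideal(s1)
  sb1 <- singular_boundary(c1[[1]], s1)
  expect_length(sb1, 1)
  expect_true(stabscape:::qp_proportional(sb1[[1]], parse_poly("a1", "a1")))

  s3 <- ode_system("x", c("a1", "a2"), "x^3 + a1*x + a2")
  c3 <- decompose_equilibrium_ideal(s3)
  sb3 <- singular_boundary(c3[[1]], s3)
  expect_length(sb3, 1)
  # oracle: resultant of f and f' by explicit Sylvester determinant
  vars <- c("a1", "a2")
  fc <- lapply(c("1", "0", "a1", "a2"), parse_poly, vars = vars)
  gc <- lapply(c("3", "0", "a1"), parse_poly, vars = vars)
  res <- sylvester_resultant(fc, gc, vars)
  expect_true(stabscape:::qp_proportional(sb3[[1]], res))
  expect_true(stabscape:::qp_proportional(
    sb3[[1]], parse_poly("4*a1^3 + 27*a2^2", vars)))
})

test_that("factor splitting decomposes simple and ecological systems", {
  s <- ode_system("x", "a", "x*(1-x)")
  comps <- decompose_equilibrium_ideal(s)
  expect_length(comps, 2)
  keys <- sort(vapply(comps, function(cm)
    paste(sort(vapply(cm$gens, qp_key, "")), collapse = ";"), ""))
  expect_equal(keys, sort(c(qp_key(parse_poly("x", c("x", "a"))),
                            qp_key(parse_poly("x - 1", c("x", "a"))))))

  lc <- fixtures("levins_culver")
  comps <- decompose_equilibrium_ideal(lc)
  expect_length(comps, 4)
  expect_setequal(vapply(comps, `[[`, "", "label"),
                  c("E_0", "E_y", "E_z", "E_co"))
  # decomposition correctness: the union of component solutions equals the
  # direct solutions of the full system at random parameter points
  set.seed(2)
  for (rep in 1:8) {
    a <- runif(4, 0.2, 3)
    names(a) <- lc$parameters
    ss <- steady_states(lc, a)  # union over components, deduplicated
    # direct check: all returned points satisfy the rates, and the expected
    # count for this binomial system (2 x 2 branches) is 4
    expect_lte(nrow(ss$points), 4)
    expect_gte(sum(ss$real), 3)
    expect_lt(max(ss$residual), 1e-8)
  }
})

test_that("the competition-colonization boundary reproduces the printed factors", {
  lc <- fixtures("levins_culver")
  arr <- total_boundary(lc, include_coordinate_hyperplanes = TRUE)
  expect_length(arr$polys, 11)
  expect_equal(sum(!arr$is_coordinate), 7)
  got <- sort(vapply(arr$polys[!arr$is_coordinate], qp_key, ""))
  want <- sort(vapply(lc_printed_factors(), qp_key, ""))
  expect_equal(got, want)
})

test_that("coordinate boundaries behave per component", {
  lc <- fixtures("levins_culver")
  comps <- decompose_equilibrium_ideal(lc)
  labs <- vapply(comps, `[[`, "", "label")
  co <- comps[[which(labs == "E_co")]]
  cb <- coordinate_boundary(co, "z")
  keys <- vapply(cb, qp_key, "")
  g6 <- qp_key(lc_printed_factors()[[6]])
  expect_true(g6 %in% keys)
  # z is identically zero on the species-1-only component: skipped
  ey <- comps[[which(labs == "E_y")]]
  cbz <- coordinate_boundary(ey, "z")
  expect_true(attr(cbz, "skipped"))
  expect_length(cbz, 0)
  # one-variable toy: x-boundary of <x - a1> is {a1}
  s <- ode_system("x", "a1", "x - a1")
  cs <- decompose_equilibrium_ideal(s)
  cbx <- coordinate_boundary(cs[[1]], "x")
  expect_true(stabscape:::qp_proportional(cbx[[1]], parse_poly("a1", "a1")))
})

test_that("a stable system with no stability boundary gives an empty set", {
  s <- ode_system("x", "a1", "a1 - x")
  cs <- decompose_equilibrium_ideal(s)
  rh <- routh_hurwitz_boundary(cs[[1]], s)
  expect_length(rh, 0)
})

test_that("the predator-prey trace boundary vanishes at the printed threshold", {
  sys <- fixtures("predator_prey_s2")
  comps <- decompose_equilibrium_ideal(sys)
  co <- comps[[which(vapply(comps, function(cm)
    length(cm$zero_vars) == 0, TRUE))[1]]]
  rh <- routh_hurwitz_boundary(co, sys)
  vals <- vapply(rh, function(f)
    stabscape:::rat_as_numeric(stabscape:::qp_eval_rat(f, list(A = rat(30, 11)))), 0)
  expect_lt(min(abs(vals)), 1e-12)
})

test_that("raw arrangements pass through normalization unchanged", {
  arr <- fixtures("two_ellipses")
  renorm <- hypersurface_arrangement(arr$polys, arr$parameters)
  expect_equal(sort(vapply(renorm$polys, qp_key, "")),
               sort(vapply(arr$polys, qp_key, "")))
  # a reducible input is split into its irreducible factors
  split <- hypersurface_arrangement(list("(a1 - 1)*(a1 - 2)^2"), c("a1", "a2"))
  expect_length(split$polys, 2)
})

test_that("the coral model decomposes into the five equilibrium types", {
  coral <- fixtures("coral_fixed")
  comps <- decompose_equilibrium_ideal(coral)
  expect_length(comps, 5)
  expect_setequal(vapply(comps, `[[`, "", "label"),
                  c("E_0", "E_x", "E_xy", "E_xz", "E_co"))
})

test_that("sampled singular-boundary points carry a singular solution", {
  # on the discriminant a2^2 = 4 a1 a3 the quadratic has a double root,
  # where f and f' vanish together
  set.seed(9)
  for (rep in 1:20) {
    a1 <- runif(1, 0.5, 2); a3 <- runif(1, 0.5, 2)
    a2 <- 2 * sqrt(a1 * a3)
    x_dbl <- -a2 / (2 * a1)
    expect_lt(abs(a1 * x_dbl^2 + a2 * x_dbl + a3), 1e-9)
    expect_lt(abs(2 * a1 * x_dbl + a2), 1e-9)  # det J = f'
  }
})
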