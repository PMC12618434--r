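# Parametric ODE systems: Jacobians, characteristic/Routh polynomials,
# stability verdicts and steady-state solving.

rat <- stabscape:::rat
rat_format <- stabscape:::rat_format

test_that("predator-prey coexistence trace/determinant are exact rationals", {
  sys <- fixtures("predator_prey_s2")
  J <- jacobian(sys)
  cp <- char_poly(J, at = list(x = rat(2), y = rat(2, 9), A = rat(9, 4)))
  # c_1 = -trace = 7/12, c_0 = det = 1/72
  expect_equal(rat_format(cp$coefficients[[2]]), "7/12")
  expect_equal(rat_format(cp$coefficients[[1]]), "1/72")
  # at the Allee threshold A = 30/11 the trace vanishes
  cp_b <- char_poly(J, at = list(x = rat(2), y = rat(8, 15), A = rat(30, 11)))
  expect_equal(rat_format(cp_b$coefficients[[2]]), "0")
  # past the boundary, A = 3: trace = 1/4 so c_1 = -1/4
  cp3 <- char_poly(J, at = list(x = rat(2), y = rat(2, 3), A = rat(3)))
  expect_equal(rat_format(cp3$coefficients[[2]]), "-1/4")
})

test_that("one-variable decay system has Jacobian [[-1]]", {
  sys <- ode_system("x", "a", "-x")
  J <- jacobian(sys)
  expect_equal(stabscape:::qrf_eval(J[[1, 1]], c(x = 0.3, a = 1)), -1)
  cp <- char_poly(J, at = list(x = rat(1), a = rat(1)))
  rp <- routh_polynomials(cp)
  expect_equal(rat_format(rp[[1]]), "1")  # positive: stable
})

test_that("characteristic polynomials match an interpolation oracle", {
  expect_equal(unlist(lapply(char_poly(-diag(2))$coefficients, identity)),
               c(1, 2, 1))
  set.seed(7)
  for (rep in 1:10) {
    J <- matrix(sample(-5:5, 9, replace = TRUE), 3, 3)
    cp <- char_poly(J)
    expect_equal(unlist(cp$coefficients), charpoly_interp(J), tolerance = 1e-12)
  }
  expect_error(char_poly(matrix(1, 2, 3)), "square")
})

test_that("Routh polynomial lists have the standard small-n forms", {
  # n = 2: (c_1, c_0); n = 3: (c_2, c_2 c_1 - c_3 c_0, c_0)
  set.seed(21)
  for (rep in 1:10) {
    J3 <- matrix(sample(-4:4, 9, replace = TRUE), 3, 3)
    cf <- unlist(char_poly(J3)$coefficients)  # c_0..c_3
    rv <- unlist(routh_polynomials(char_poly(J3)))
    expect_equal(rv, c(cf[3], cf[3] * cf[2] - cf[4] * cf[1], cf[1]),
                 tolerance = 1e-12)
    J2 <- matrix(sample(-4:4, 4, replace = TRUE), 2, 2)
    cf2 <- unlist(char_poly(J2)$coefficients)
    expect_equal(unlist(routh_polynomials(char_poly(J2))), cf2[c(2, 1)],
                 tolerance = 1e-12)
  }
  nm <- char_poly(2 * diag(2)); nm$coefficients[[3]] <- 2
  expect_error(routh_polynomials(nm), "monic")
})

test_that("Routh-Hurwitz verdicts agree with eigenvalue verdicts", {
  sys <- fixtures("predator_prey_s2")
  J <- jacobian(sys)
  Jn <- stabscape:::sym_matrix_eval(J, matrix(c(2, 2/9, 9/4), 1,
        dimnames = list(NULL, c("x", "y", "A"))))
  expect_equal(as.character(is_stable(Jn)), "stable")
  Jn3 <- stabscape:::sym_matrix_eval(J, matrix(c(2, 2/3, 3), 1,
        dimnames = list(NULL, c("x", "y", "A"))))
  expect_equal(as.character(is_stable(Jn3)), "unstable")
  expect_equal(as.character(is_stable(-diag(3))), "stable")
  # property: random rational matrices, sizes 2-3
  set.seed(5)
  for (rep in 1:300) {
    n <- sample(2:3, 1)
    M <- matrix(sample(-6:6, n * n, replace = TRUE) / sample(1:3, n * n, TRUE), n, n)
    v <- is_stable(M)
    ev <- attr(v, "eigen")
    if (as.character(v) != "boundary" && ev != "boundary")
      expect_equal(as.character(v), ev)
  }
})

test_that("steady states of the predator-prey model match the worked example", {
  sys <- fixtures("predator_prey_s2")
  expect_warning(ss <- steady_states(sys, c(A = 9/4)), "denominator")
  pts <- Re(ss$points[ss$real, , drop = FALSE])
  expect_equal(nrow(pts), 4)
  # extinction, prey-only at A and K, and coexistence (2, 2/9)
  d <- function(p) min(sqrt(rowSums(sweep(pts, 2, p)^2)))
  expect_lt(d(c(0, 0)), 1e-8)
  expect_lt(d(c(9/4, 0)), 1e-8)
  expect_lt(d(c(1, 0)), 1e-8)
  expect_lt(d(c(2, 2/9)), 1e-8)
  expect_lt(max(ss$residual), 1e-8)
  co <- which(ss$positive)
  expect_equal(as.character(ss$stability[[co]]), "stable")
})

test_that("coexistence solution matches the closed form", {
  lc <- fixtures("levins_culver")
  set.seed(3)
  for (rep in 1:6) {
    a <- c(beta_y = runif(1, 1, 3), beta_z = runif(1, 0.5, 3),
           gamma_y = runif(1, 0.1, 0.9), gamma_z = runif(1, 0.1, 2))
    ss <- steady_states(lc, a)
    y_star <- 1 - a["gamma_y"] / a["beta_y"]
    z_star <- a["gamma_y"] / a["beta_y"] -
      (a["gamma_z"] + a["beta_y"] - a["gamma_y"]) / a["beta_z"]
    pts <- Re(ss$points[ss$real, , drop = FALSE])
    expect_lt(min(sqrt(rowSums(sweep(pts, 2, c(y_star, z_star))^2))), 1e-8)
    # extinction is always a steady state
    expect_lt(min(sqrt(rowSums(pts^2))), 1e-8)
    expect_lt(max(ss$residual), 1e-8)
  }
})

test_that("symbolic characteristic coefficients satisfy the trace/det identities", {
  for (nm in c("levins_culver", "coral_fixed")) {
    sys <- fixtures(nm)
    J <- jacobian(sys)
    cp <- char_poly(J)
    n <- length(sys$variables)
    set.seed(17)
    pt <- runif(n + length(sys$parameters), 0.3, 2)
    names(pt) <- c(sys$variables, sys$parameters)
    A <- matrix(pt, 1, dimnames = list(NULL, names(pt)))
    Jn <- stabscape:::sym_matrix_eval(J, A)
    cn1 <- stabscape:::qrf_eval(cp$coefficients[[n]], A)
    c0 <- stabscape:::qrf_eval(cp$coefficients[[1]], A)
    expect_equal(unname(cn1), -sum(diag(Jn)), tolerance = 1e-10)
    expect_equal(unname(c0), (-1)^n * det(Jn), tolerance = 1e-10)
  }
})
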