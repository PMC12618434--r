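# Exact rational arithmetic and the sparse polynomial engine.

rat <- stabscape:::rat
rat_parse <- stabscape:::rat_parse
rat_format <- stabscape:::rat_format
parse_poly <- stabscape:::parse_poly
parse_ratfun <- stabscape:::parse_ratfun

test_that("rational arithmetic is exact and reduced", {
  a <- rat_parse("3/4"); b <- rat_parse("-7/12")
  s <- stabscape:::rat_add(a, b)
  expect_equal(rat_format(s), "1/6")
  p <- stabscape:::rat_mul(rat_parse("2/3"), rat_parse("9/4"))
  expect_equal(rat_format(p), "3/2")
  q <- stabscape:::rat_div(rat(1), rat_parse("-5/3"))
  expect_equal(rat_format(q), "-3/5")
  expect_true(all(stabscape:::rat_eq(stabscape:::rat_pow(rat_parse("2/3"), 3),
                                     rat_parse("8/27"))))
  expect_error(rat_parse("0.5"), "non-integer")
  expect_error(rat(1, 0), "zero denominator")
})

test_that("polynomial parsing is exact and rejects floats/unknowns", {
  p <- parse_poly("(a1-5)^2 + 4*(a2-5)^2 - 16", c("a1", "a2"))
  expect_equal(stabscape:::qp_string(p), "a1^2 + 4*a2^2 - 10*a1 - 40*a2 + 109")
  expect_equal(unname(stabscape:::qp_eval(p, c(a1 = 5, a2 = 5))), -16)
  q <- parse_poly("x^2/4 - 1/2", "x")
  expect_equal(rat_format(q$coef), c("1/4", "-1/2"))
  expect_error(parse_poly("0.5*x", "x"), "float literal")
  expect_error(parse_poly("x + y", "x"), "undeclared symbol")
  # sympy-style double-star powers are accepted
  expect_true(stabscape:::qp_proportional(parse_poly("x**2 - 1", "x"),
                                          parse_poly("x^2 - 1", "x")))
})

test_that("polynomial derivatives match central finite differences", {
  set.seed(11)
  sys <- ode_system(c("u", "v"), "a",
                    c("u^3 - 2*u*v + a*v^2 - 1/2", "3*u^2*v - v^3 + a*u"))
  J <- jacobian(sys)
  for (rep in 1:20) {
    pt <- c(u = runif(1, -2, 2), v = runif(1, -2, 2), a = runif(1, 0.5, 2))
    Jnum <- stabscape:::sym_matrix_eval(J, matrix(pt, 1, dimnames = list(NULL, names(pt))))
    Jfd <- fd_jacobian(sys, pt)
    expect_lt(max(abs(Jnum - Jfd)) / (1 + max(abs(Jnum))), 1e-6)
  }
})

test_that("exact rational evaluation and unit-multiple detection work", {
  p <- parse_poly("2*x^2*y - 4*y + 6", c("x", "y"))
  v <- stabscape:::qp_eval_rat(p, list(x = rat_parse("1/2"), y = rat_parse("3")))
  expect_equal(rat_format(v), "-9/2")
  q <- stabscape:::qp_scale(p, rat_parse("-7/3"))
  expect_true(stabscape:::qp_proportional(p, q))
  r <- parse_poly("2*x^2*y - 4*y + 5", c("x", "y"))
  expect_false(stabscape:::qp_proportional(p, r))
})

test_that("rational-function rates evaluate exactly at rational points", {
  f <- parse_ratfun("y*(-m + g*x/(1 + b*x))", c("x", "y", "m", "g", "b"))
  v <- stabscape:::qrf_eval_rat(f, list(x = rat(2), y = rat(1), m = rat_parse("1/2"),
                                        g = rat(1), b = rat_parse("3/2")))
  expect_equal(rat_format(v), "0")
})
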