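# Rational functions as pairs of qpoly (no gcd cancellation; denominators
# stay factored as built, which is sufficient for exact evaluation and
# differentiation of model Jacobians).

qrf <- function(num, den = NULL) {
  if (is.null(den)) den <- qp_const(num$vars, 1)
  structure(list(num = num, den = den), class = "qrf")
}

qrf_align <- function(x, y) {
  vars <- union(x$num$vars, y$num$vars)
  list(
    x = qrf(qp_align(x$num, vars), qp_align(x$den, vars)),
    y = qrf(qp_align(y$num, vars), qp_align(y$den, vars))
  )
}

qrf_add <- function(x, y) {
  a <- qrf_align(x, y)
  qrf(qp_add(qp_mul(a$x$num, a$y$den), qp_mul(a$y$num, a$x$den)),
      qp_mul(a$x$den, a$y$den))
}

qrf_neg <- function(x) qrf(qp_neg(x$num), x$den)
qrf_sub <- function(x, y) qrf_add(x, qrf_neg(y))

qrf_mul <- function(x, y) {
  a <- qrf_align(x, y)
  qrf(qp_mul(a$x$num, a$y$num), qp_mul(a$x$den, a$y$den))
}

qrf_div <- function(x, y) {
  if (qp_is_zero(y$num)) stop("division by zero expression", call. = FALSE)
  a <- qrf_align(x, y)
  qrf(qp_mul(a$x$num, a$y$den), qp_mul(a$x$den, a$y$num))
}

qrf_pow <- function(x, n) {
  if (n < 0) return(qrf_pow(qrf_div(qrf(qp_const(x$num$vars, 1)), x), -n))
  qrf(qp_pow(x$num, n), qp_pow(x$den, n))
}

qrf_deriv <- function(x, var) {
  # (n/d)' = (n'd - nd')/d^2
  qrf(qp_sub(qp_mul(qp_deriv(x$num, var), x$den),
             qp_mul(x$num, qp_deriv(x$den, var))),
      qp_mul(x$den, x$den))
}

qrf_is_poly <- function(x) qp_is_const(x$den)

# coerce to qpoly (denominator must be a nonzero constant)
qrf_as_poly <- function(x) {
  if (!qrf_is_poly(x)) stop("expression is not polynomial", call. = FALSE)
  d <- if (qp_is_zero(x$den)) stop("zero denominator", call. = FALSE)
       else rat_slice(x$den$coef, 1)
  qp_scale(x$num, rat(d$den, d$num))
}

qrf_eval <- function(x, A) {
  qp_eval(x$num, A) / qp_eval(x$den, A)
}

qrf_eval_rat <- function(x, point) {
  rat_div(qp_eval_rat(x$num, point), qp_eval_rat(x$den, point))
}

qrf_subs_rat <- function(x, values) {
  qrf(qp_subs_rat(x$num, values), qp_subs_rat(x$den, values))
}

#' @export
print.qrf <- function(x, ...) {
  if (qrf_is_poly(x)) print(qrf_as_poly(x))
  else cat("(", qp_string(x$num), ") / (", qp_string(x$den), ")\n")
  invisible(x)
}

# ---- expression parser ------------------------------------------------------

#' Parse a rational expression with exact arithmetic
#'
#' Grammar: identifiers (declared in `vars`), integer literals, rationals
#' written as `p/q`, the operators `+ - * / ^` (integer exponents) and
#' parentheses. Float literals such as `0.5` are rejected; write `1/2`.
#'
#' @param text expression string.
#' @param vars character vector of admissible identifiers.
#' @return a `qrf` rational function over `vars`.
#' @keywords internal
parse_ratfun <- function(text, vars) {
  expr <- tryCatch(parse(text = text, keep.source = FALSE)[[1]],
                   error = function(e) stop("parse error in: ", text, call. = FALSE))
  walk <- function(e) {
    if (is.numeric(e)) {
      if (length(e) != 1 || e != round(e))
        stop("float literal '", e, "' not allowed; use exact rationals like 1/2",
             call. = FALSE)
      return(qrf(qp_const(vars, rat(e))))
    }
    if (is.name(e)) {
      nm <- as.character(e)
      if (!nm %in% vars)
        stop("undeclared symbol '", nm, "' in expression: ", text, call. = FALSE)
      return(qrf(qp_var(vars, nm)))
    }
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (op == "(") return(walk(e[[2]]))
      if (op == "-" && length(e) == 2) return(qrf_neg(walk(e[[2]])))
      if (op == "+" && length(e) == 2) return(walk(e[[2]]))
      if (length(e) == 3) {
        if (op == "^") {
          ex <- e[[3]]
          neg <- FALSE
          if (is.call(ex) && as.character(ex[[1]]) == "-" && length(ex) == 2) {
            neg <- TRUE; ex <- ex[[2]]
          }
          if (!is.numeric(ex) || ex != round(ex))
            stop("exponent must be an integer in: ", text, call. = FALSE)
          return(qrf_pow(walk(e[[2]]), if (neg) -ex else ex))
        }
        l <- walk(e[[2]]); r <- walk(e[[3]])
        return(switch(op,
          "+" = qrf_add(l, r),
          "-" = qrf_sub(l, r),
          "*" = qrf_mul(l, r),
          "/" = qrf_div(l, r),
          stop("unsupported operator '", op, "' in: ", text, call. = FALSE)))
      }
    }
    stop("unsupported construct in expression: ", text, call. = FALSE)
  }
  walk(expr)
}

#' Parse a polynomial expression (division only by constants)
#' @keywords internal
parse_poly <- function(text, vars) {
  # sympy prints powers as **; accept both
  qrf_as_poly(parse_ratfun(gsub("**", "^", text, fixed = TRUE), vars))
}
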