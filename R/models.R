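# Parametric ODE systems: symbolic representation, Jacobians, characteristic
# and Routh polynomials, steady-state solving and stability classification.

#' Define a parametric ODE system
#'
#' Represents \eqn{\dot x = f(x; a)} with rational rate functions \eqn{f}
#' over the variables \eqn{x} and positive parameters \eqn{a}. Rates are
#' parsed with exact rational arithmetic: integer literals and fractions
#' like `1/2` are allowed, float literals are rejected.
#'
#' @param variables ordered character vector of state variable names.
#' @param parameters ordered character vector of parameter names.
#' @param rates character vector (one expression per variable) over
#'   `c(variables, parameters)`; polynomial or rational.
#' @param fixed optional named list/vector of exact rational constants
#'   (e.g. `list(d = "1", beta_y = "5")`) substituted into the rates; the
#'   named parameters are removed from `parameters`.
#' @param name optional model name.
#' @return an object of class `ode_system`.
#' @examples
#' lv <- ode_system(c("y", "z"), c("beta_y", "beta_z", "gamma_y", "gamma_z"),
#'                  c("beta_y*y*(1-y) - gamma_y*y",
#'                    "beta_z*z*(1-y-z) - beta_y*y*z - gamma_z*z"))
#' @export
ode_system <- function(variables, parameters, rates, fixed = NULL, name = NULL) {
  stopifnot(length(variables) >= 1, length(rates) == length(variables))
  rates_text <- as.character(rates)
  parameters_all <- parameters
  fixed_text <- if (length(fixed)) {
    stats::setNames(vapply(fixed, function(v)
      if (inherits(v, "rat")) rat_format(v) else as.character(v), ""), names(fixed))
  } else NULL
  syms <- c(variables, parameters)
  if (anyDuplicated(syms)) stop("duplicate symbol names", call. = FALSE)
  rfs <- lapply(rates, parse_ratfun, vars = syms)
  fixed_rat <- list()
  if (length(fixed)) {
    fixed_rat <- lapply(fixed, function(v) if (inherits(v, "rat")) v else rat_parse(v))
    names(fixed_rat) <- names(fixed)
    stopifnot(all(names(fixed_rat) %in% parameters))
    rfs <- lapply(rfs, qrf_subs_rat, values = fixed_rat)
    parameters <- setdiff(parameters, names(fixed_rat))
  }
  if (length(parameters) < 1)
    stop("at least one free parameter is required", call. = FALSE)
  for (f in rfs) if (qp_is_zero(f$den)) stop("zero rate denominator", call. = FALSE)
  # align all rates over the reduced symbol set
  syms <- c(variables, parameters)
  rfs <- lapply(rfs, function(f) qrf(qp_align(f$num, syms), qp_align(f$den, syms)))
  structure(list(variables = variables, parameters = parameters,
                 rates = rfs, fixed = fixed_rat, name = name,
                 rates_text = rates_text, parameters_all = parameters_all,
                 fixed_text = as.list(fixed_text),
                 cache = new.env(parent = emptyenv())),
            class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  cat("Parametric ODE system", if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat("  variables: ", paste(x$variables, collapse = ", "), "\n")
  cat("  parameters:", paste(x$parameters, collapse = ", "), "\n")
  for (i in seq_along(x$variables)) {
    cat("  d", x$variables[i], "/dt = ", sep = "")
    if (qrf_is_poly(x$rates[[i]])) cat(qp_string(qrf_as_poly(x$rates[[i]])), "\n")
    else cat("(", qp_string(x$rates[[i]]$num), ") / (",
             qp_string(x$rates[[i]]$den), ")\n")
  }
  invisible(x)
}

#' Symbolic Jacobian of the rate functions
#'
#' @param sys an [ode_system].
#' @return an `n x n` list-matrix of rational functions; entry (i, j) is the
#'   partial derivative of rate i with respect to variable j.
#' @export
jacobian <- function(sys) {
  n <- length(sys$variables)
  J <- vector("list", n * n)
  dim(J) <- c(n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      J[[i, j]] <- qrf_deriv(sys$rates[[i]], sys$variables[j])
  structure(J, class = c("sym_matrix", "matrix"))
}

# evaluate a symbolic list-matrix at an exact rational point
sym_matrix_eval_rat <- function(J, point) {
  n <- nrow(J)
  M <- vector("list", n * n); dim(M) <- c(n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    M[[i, j]] <- qrf_eval_rat(J[[i, j]], point)
  M
}

sym_matrix_eval <- function(J, point) {
  n <- nrow(J)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    M[i, j] <- qrf_eval(J[[i, j]], point)
  M
}

# ---- characteristic polynomial ---------------------------------------------

# generic scalar ops so the same minors formulas serve numeric doubles,
# exact rationals and symbolic rational functions
sc_ops <- function(proto) {
  if (inherits(proto, "qrf")) {
    list(add = qrf_add, mul = qrf_mul, neg = qrf_neg,
         zero = qrf(qp_zero(proto$num$vars)), one = qrf(qp_const(proto$num$vars, 1)))
  } else if (inherits(proto, "rat")) {
    list(add = rat_add, mul = rat_mul, neg = rat_neg, zero = rat(0), one = rat(1))
  } else {
    list(add = `+`, mul = `*`, neg = function(x) -x, zero = 0, one = 1)
  }
}

m_get <- function(M, i, j) if (is.list(M)) M[[i, j]] else M[i, j]

# sum of principal k x k minors via cofactor expansion (n <= 4)
principal_minor_sum <- function(M, k, ops) {
  n <- if (is.list(M)) dim(M)[1] else nrow(M)
  dets <- ops$zero
  idx <- utils::combn(n, k)
  # direct Leibniz expansion over k! permutations (k <= 4 keeps this tiny)
  perm <- perms(k)
  for (ci in seq_len(ncol(idx))) {
    rows <- idx[, ci]
    for (pi in seq_len(nrow(perm))) {
      p <- perm[pi, ]
      term <- ops$one
      for (r in seq_len(k)) term <- ops$mul(term, m_get(M, rows[r], rows[p[r]]))
      if (perm_sign(p) < 0) term <- ops$neg(term)
      dets <- ops$add(dets, term)
    }
  }
  dets
}

perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- perms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, matrix(setdiff(seq_len(k), i)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

perm_sign <- function(p) {
  s <- 1
  for (i in seq_along(p)) for (j in seq_along(p)) if (i < j && p[i] > p[j]) s <- -s
  s
}

#' Characteristic polynomial of a Jacobian matrix
#'
#' Computes the monic characteristic polynomial
#' \eqn{\det(\lambda I - J) = \lambda^n + c_{n-1}\lambda^{n-1} + \dots + c_0}.
#' Coefficients are exact (rational or symbolic) whenever the input is; by
#' construction \eqn{c_{n-1} = -\mathrm{tr}(J)} and
#' \eqn{c_0 = (-1)^n \det(J)}.
#'
#' @param J a square matrix: numeric, a list-matrix of `rat`, or a symbolic
#'   list-matrix as returned by [jacobian()].
#' @param at optional point (named list of exact rationals, or named numeric
#'   vector) at which a symbolic `J` is evaluated first.
#' @return object of class `char_poly` with field `coefficients`
#'   (list `c_0, ..., c_n`, ascending).
#' @export
char_poly <- function(J, at = NULL) {
  if (inherits(J, "sym_matrix") && !is.null(at)) {
    J <- if (is.numeric(at)) sym_matrix_eval(J, matrix(at, 1, dimnames = list(NULL, names(at))))
         else sym_matrix_eval_rat(J, at)
  }
  n <- if (is.list(J)) dim(J)[1] else nrow(J)
  nc <- if (is.list(J)) dim(J)[2] else ncol(J)
  if (n != nc) stop("char_poly requires a square matrix", call. = FALSE)
  if (n > 4) stop("characteristic polynomials implemented for n <= 4", call. = FALSE)
  ops <- sc_ops(m_get(J, 1, 1))
  # c_{n-k} = (-1)^k e_k where e_k = sum of principal k-minors
  coefs <- vector("list", n + 1)
  coefs[[n + 1]] <- ops$one
  for (k in seq_len(n)) {
    ek <- principal_minor_sum(J, k, ops)
    coefs[[n - k + 1]] <- if (k %% 2 == 1) ops$neg(ek) else ek
  }
  structure(list(n = n, coefficients = coefs), class = "char_poly")
}

#' @export
print.char_poly <- function(x, ...) {
  cat("monic characteristic polynomial, degree", x$n, "\n")
  for (i in rev(seq_len(x$n))) {
    ci <- x$coefficients[[i]]
    lab <- paste0("  c_", i - 1, " = ")
    if (inherits(ci, "rat")) cat(lab, rat_format(ci), "\n")
    else if (inherits(ci, "qrf")) { cat(lab); print(ci) }
    else cat(lab, format(ci), "\n")
  }
  invisible(x)
}

# Hurwitz matrix H[i, j] = c_{n - 2i + j} (1-based), out-of-range = 0
hurwitz_matrix_index <- function(n) {
  outer(seq_len(n), seq_len(n), function(i, j) n - 2 * i + j)
}

#' Routh polynomials of a monic characteristic polynomial
#'
#' Returns the quantities whose joint positivity is the Routh-Hurwitz
#' stability criterion: the leading principal minors
#' \eqn{\Delta_1, \dots, \Delta_{n-1}} of the Hurwitz matrix together with
#' \eqn{c_0} (using \eqn{\Delta_n = c_0 \Delta_{n-1}}). For small systems
#' this reduces to the familiar lists: `c(c_1, c_0)` for n = 2 and
#' `c(c_2, c_2*c_1 - c_3*c_0, c_0)` for n = 3.
#'
#' @param cp a `char_poly` (monic).
#' @return list of n Routh polynomials (same coefficient type as `cp`).
#' @export
routh_polynomials <- function(cp) {
  stopifnot(inherits(cp, "char_poly"))
  n <- cp$n
  if (n > 4) stop("Routh polynomials implemented for n <= 4", call. = FALSE)
  cf <- cp$coefficients
  ops <- sc_ops(cf[[1]])
  cn <- cf[[n + 1]]
  monic <- if (is.numeric(cn)) isTRUE(all.equal(cn, 1))
           else if (inherits(cn, "rat")) cn$num == 1 && cn$den == 1
           else qp_is_const(cn$num) && qp_proportional(cn$num, cn$den)
  if (!monic) stop("routh_polynomials requires a monic characteristic polynomial",
                   call. = FALSE)
  cidx <- function(i) if (i < 0 || i > n) ops$zero else cf[[i + 1]]
  if (n == 1) return(list(cidx(0)))
  if (n == 2) return(list(cidx(1), cidx(0)))
  if (n == 3) return(list(cidx(2),
                          ops$add(ops$mul(cidx(2), cidx(1)),
                                  ops$neg(ops$mul(cidx(3), cidx(0)))),
                          cidx(0)))
  # n = 4: minors of the Hurwitz matrix
  H <- hurwitz_matrix_index(n)
  getH <- function(i, j) cidx(H[i, j])
  d1 <- getH(1, 1)
  d2 <- ops$add(ops$mul(getH(1, 1), getH(2, 2)),
                ops$neg(ops$mul(getH(1, 2), getH(2, 1))))
  # Delta_3 by cofactor expansion of the leading 3x3 block
  d3 <- ops$zero
  signs <- c(1, -1, 1)
  for (j in 1:3) {
    cols <- setdiff(1:3, j)
    sub <- ops$add(ops$mul(getH(2, cols[1]), getH(3, cols[2])),
                   ops$neg(ops$mul(getH(2, cols[2]), getH(3, cols[1]))))
    term <- ops$mul(getH(1, j), sub)
    if (signs[j] < 0) term <- ops$neg(term)
    d3 <- ops$add(d3, term)
  }
  list(d1, d2, d3, cidx(0))
}

#' Stability verdict for a numeric Jacobian
#'
#' Classifies a steady state as `"stable"`, `"unstable"` or `"boundary"`
#' using the Routh-Hurwitz criterion (all Routh polynomials positive), and
#' cross-checks against the eigenvalue real parts.
#'
#' @param J numeric square matrix, or list-matrix of exact rationals.
#' @param tol tolerance on Routh-polynomial values; values within `tol` of 0
#'   give the verdict `"boundary"`.
#' @return character verdict with attributes `routh` (numeric values) and
#'   `eigen` (eigenvalue verdict).
#' @export
is_stable <- function(J, tol = 1e-9) {
  cp <- char_poly(J)
  rv <- routh_polynomials(cp)
  vals <- vapply(rv, function(v) if (inherits(v, "rat")) rat_as_numeric(v) else v, 0)
  verdict <- if (all(vals > tol)) "stable"
             else if (any(vals < -tol)) "unstable"
             else "boundary"
  Jn <- if (is.list(J)) {
    n <- dim(J)[1]
    matrix(vapply(seq_len(n * n), function(i) rat_as_numeric(J[[i]]), 0), n, n)
  } else J
  re <- max(Re(eigen(Jn, only.values = TRUE)$values))
  ev <- if (re < -tol) "stable" else if (re > tol) "unstable" else "boundary"
  if (verdict != ev && verdict != "boundary" && ev != "boundary")
    warning("Routh and eigenvalue verdicts disagree (", verdict, " vs ", ev, ")")
  structure(verdict, routh = vals, eigen = ev)
}

# ---- steady states ----------------------------------------------------------

# polynomial system (numerators of the rates) as qpoly in variables+parameters
rate_numerators <- function(sys) lapply(sys$rates, function(f) f$num)

sys_decomposition <- function(sys) {
  if (!is.null(sys$cache$decomp)) return(sys$cache$decomp)
  sys$cache$decomp <- decompose_equilibrium_ideal(sys)
  sys$cache$decomp
}

# solve one component's generators at fixed numeric parameters; returns a
# complex matrix of solutions (possibly with repeats = multiplicity)
solve_component_numeric <- function(gens_np, vars, tol = 1e-9) {
  sols <- list()
  recurse <- function(gens, assigned) {
    gens <- Filter(function(g) nrow(g$E) > 0 || TRUE, gens)
    if (!length(gens)) {
      if (length(assigned) == length(vars)) {
        sols[[length(sols) + 1]] <<- assigned[vars]
      } else {
        stop("component is not zero-dimensional at this parameter point",
             call. = FALSE)
      }
      return(invisible())
    }
    # substitute assigned values
    cur <- lapply(gens, function(g) {
      sub <- intersect(names(assigned), g$vars)
      if (length(sub)) np_subs(g, assigned[sub]) else g
    })
    used <- lapply(cur, np_nvars_used)
    nuse <- lengths(used)
    if (any(nuse == 0)) {
      vals <- vapply(cur[nuse == 0], np_const_val, 0 + 0i)
      if (any(Mod(vals) > tol)) return(invisible())  # inconsistent branch
      cur <- cur[nuse > 0]; used <- used[nuse > 0]; nuse <- nuse[nuse > 0]
      if (!length(cur)) {
        free <- setdiff(vars, names(assigned))
        if (length(free))
          stop("component is not zero-dimensional at this parameter point",
               call. = FALSE)
        sols[[length(sols) + 1]] <<- assigned[vars]
        return(invisible())
      }
    }
    uni <- which(nuse == 1)
    if (!length(uni))
      stop("no univariate generator available; triangular solve failed",
           call. = FALSE)
    g <- cur[[uni[1]]]
    v <- used[[uni[1]]]
    cfs <- np_uni_coeffs(g, v)
    while (length(cfs) > 1 && Mod(cfs[length(cfs)]) < 1e-14 * max(Mod(cfs)))
      cfs <- cfs[-length(cfs)]
    if (length(cfs) <= 1) return(invisible())
    roots <- polyroot(cfs)
    rest <- cur[-uni[1]]
    for (r in roots) {
      a2 <- c(assigned, stats::setNames(as.complex(r), v))
      recurse(rest, a2)
    }
    invisible()
  }
  gens_c <- lapply(gens_np, function(g) { g$coef <- as.complex(g$coef); g })
  recurse(gens_c, stats::setNames(complex(0), character(0)))
  if (!length(sols)) return(matrix(complex(0), 0, length(vars),
                                   dimnames = list(NULL, vars)))
  do.call(rbind, lapply(sols, function(s) matrix(s, 1, dimnames = list(NULL, vars))))
}

#' Solve for the steady states of a system at fixed parameter values
#'
#' Clears denominators, decomposes the equilibrium ideal into components
#' (cached per system), solves each component exactly-in-structure
#' (triangular back-substitution with univariate root finding) and merges
#' the solutions. Every returned point is residual-checked against the
#' original rates; solutions hitting a rate denominator's zero set are
#' dropped and reported.
#'
#' @param sys an [ode_system].
#' @param a_star named parameter values: numeric vector, or list of exact
#'   rationals/strings.
#' @param tol solver/residual tolerance.
#' @param pos_tol strict-positivity tolerance for the positive subset.
#' @return object of class `steady_state_set`: list with `points` (complex
#'   matrix), `real` and `positive` logical flags, `residual`, and for real
#'   nonnegative points `stability` verdicts with Routh values.
#' @export
steady_states <- function(sys, a_star, tol = 1e-9, pos_tol = 1e-9) {
  avals <- if (is.list(a_star)) {
    vapply(a_star, function(v) if (inherits(v, "rat")) rat_as_numeric(v)
           else if (is.character(v)) rat_as_numeric(rat_parse(v)) else as.double(v), 0)
  } else a_star
  stopifnot(all(sys$parameters %in% names(avals)))
  avals <- avals[sys$parameters]
  decomp <- sys_decomposition(sys)
  pts <- NULL
  for (comp in decomp) {
    gens_np <- lapply(comp$gens, function(g) np_from_qp(g, avals))
    sol <- solve_component_numeric(gens_np, sys$variables, tol = tol)
    pts <- rbind(pts, sol)
  }
  if (is.null(pts)) pts <- matrix(complex(0), 0, length(sys$variables))
  # dedupe across components
  if (nrow(pts) > 1) {
    keep <- rep(TRUE, nrow(pts))
    for (i in seq_len(nrow(pts))) {
      if (!keep[i]) next
      for (j in seq_len(i - 1)) {
        if (keep[j] && sqrt(sum(Mod(pts[i, ] - pts[j, ])^2)) <
            1e-8 * (1 + sqrt(sum(Mod(pts[j, ])^2)))) { keep[i] <- FALSE; break }
      }
    }
    pts <- pts[keep, , drop = FALSE]
  }
  colnames(pts) <- sys$variables
  # residual check against the original rates; denominator collision check
  resid <- den_bad <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (max(abs(Im(pts[i, ]))) < tol) {
      point <- c(Re(pts[i, ]), avals)
      A <- matrix(point, 1, dimnames = list(NULL, names(point)))
      resid[i] <- max(abs(vapply(sys$rates, function(f) qrf_eval(f, A), 0)))
      den_bad[i] <- min(abs(vapply(sys$rates, function(f) qp_eval(f$den, A), 0)))
    } else {
      # complex residual on the cleared numerators
      point <- c(pts[i, ], as.complex(avals))
      names(point) <- c(sys$variables, sys$parameters)
      resid[i] <- max(Mod(vapply(rate_numerators(sys), function(p) {
        npp <- np_from_qp(p); npp$coef <- as.complex(npp$coef)
        np_eval_complex(npp, point)
      }, 0 + 0i)))
      den_bad[i] <- Inf
    }
  }
  dropped <- den_bad < tol
  if (any(dropped))
    warning(sum(dropped), " solution(s) collide with a rate denominator zero set",
            call. = FALSE)
  pts <- pts[!dropped, , drop = FALSE]
  resid <- resid[!dropped]
  is_real <- apply(pts, 1, function(p) max(abs(Im(p))) < 1e-6)
  is_pos <- is_real & apply(pts, 1, function(p) all(Re(p) > pos_tol))
  J <- sys_jacobian_cached(sys)
  stability <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!is_real[i] || any(Re(pts[i, ]) < -1e-6)) next
    point <- c(pmax(Re(pts[i, ]), 0), avals)
    A <- matrix(point, 1, dimnames = list(NULL, names(point)))
    Jn <- matrix(0, length(sys$variables), length(sys$variables))
    for (r in seq_len(nrow(Jn))) for (cc in seq_len(ncol(Jn)))
      Jn[r, cc] <- qrf_eval(J[[r, cc]], A)
    stability[[i]] <- is_stable(Jn)
  }
  structure(list(points = pts, real = is_real, positive = is_pos,
                 residual = resid, stability = stability,
                 parameters = avals, variables = sys$variables),
            class = "steady_state_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

np_eval_complex <- function(p, point) {
  v <- point[p$vars]
  out <- 0 + 0i
  for (t in seq_len(nrow(p$E))) {
    term <- p$coef[t]
    for (j in which(p$E[t, ] > 0)) term <- term * v[j]^p$E[t, j]
    out <- out + term
  }
  out
}

sys_jacobian_cached <- function(sys) {
  if (is.null(sys$cache$J)) sys$cache$J <- jacobian(sys)
  sys$cache$J
}

#' @export
print.steady_state_set <- function(x, ...) {
  cat("steady states:", nrow(x$points), "found,",
      sum(x$real), "real,", sum(x$positive), "strictly positive\n")
  for (i in seq_len(nrow(x$points))) {
    p <- x$points[i, ]
    lab <- if (x$real[i]) paste0("(", paste(signif(Re(p), 6), collapse = ", "), ")")
           else paste0("(", paste(format(signif(p, 4)), collapse = ", "), ")")
    st <- if (!is.null(x$stability[[i]])) paste0(" [", x$stability[[i]], "]") else ""
    cat(" ", lab, st, "\n", sep = "")
  }
  invisible(x)
}
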