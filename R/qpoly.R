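# Sparse multivariate polynomials with exact rational coefficients.
#
# A `qpoly` is list(vars, E, coef): `vars` the ordered indeterminate names,
# `E` an nterm x nvar exponent matrix and `coef` a `rat` vector. Terms are
# kept in a canonical order (total degree, then exponents, descending) so
# that string keys are usable for deduplication and identity tests.

qp_new <- function(vars, E, coef) {
  E <- matrix(as.double(E), ncol = length(vars))
  colnames(E) <- vars
  p <- structure(list(vars = vars, E = E, coef = coef), class = "qpoly")
  qp_canon(p)
}

qp_canon <- function(p) {
  if (nrow(p$E) == 0) return(p)
  key <- apply(p$E, 1, paste, collapse = ",")
  if (anyDuplicated(key)) {
    idx <- split(seq_along(key), key)
    E2 <- matrix(0, length(idx), ncol(p$E), dimnames = list(NULL, p$vars))
    num <- den <- numeric(length(idx))
    for (i in seq_along(idx)) {
      rows <- idx[[i]]
      E2[i, ] <- p$E[rows[1], ]
      s <- rat(0)
      for (r in rows) s <- rat_add(s, rat_slice(p$coef, r))
      num[i] <- s$num; den[i] <- s$den
    }
    p$E <- E2; p$coef <- rat(num, den)
  }
  keep <- p$coef$num != 0
  p$E <- p$E[keep, , drop = FALSE]
  p$coef <- rat_slice(p$coef, keep)
  if (nrow(p$E) > 1) {
    td <- rowSums(p$E)
    ord <- do.call(order, c(list(-td), lapply(seq_len(ncol(p$E)), function(j) -p$E[, j])))
    p$E <- p$E[ord, , drop = FALSE]
    p$coef <- rat_slice(p$coef, ord)
  }
  p
}

qp_zero <- function(vars) qp_new(vars, matrix(0, 0, length(vars)), rat(numeric(0)))

qp_const <- function(vars, r) {
  if (is.numeric(r)) r <- rat(r)
  qp_new(vars, matrix(0, 1, length(vars)), r)
}

qp_var <- function(vars, name) {
  stopifnot(name %in% vars)
  E <- matrix(0, 1, length(vars))
  E[1, match(name, vars)] <- 1
  qp_new(vars, E, rat(1))
}

qp_is_zero <- function(p) nrow(p$E) == 0
qp_is_const <- function(p) nrow(p$E) == 0 || all(p$E == 0)

qp_align <- function(p, vars) {
  if (identical(p$vars, vars)) return(p)
  stopifnot(all(p$vars %in% vars))
  E <- matrix(0, nrow(p$E), length(vars), dimnames = list(NULL, vars))
  E[, p$vars] <- p$E
  qp_new(vars, E, p$coef)
}

qp_add <- function(p, q) {
  if (!identical(p$vars, q$vars)) {
    vars <- union(p$vars, q$vars)
    p <- qp_align(p, vars); q <- qp_align(q, vars)
  }
  qp_new(p$vars, rbind(p$E, q$E), rat(c(p$coef$num, q$coef$num), c(p$coef$den, q$coef$den)))
}

qp_neg <- function(p) { p$coef <- rat_neg(p$coef); p }
qp_sub <- function(p, q) qp_add(p, qp_neg(q))

qp_scale <- function(p, r) {
  if (is.numeric(r)) r <- rat(r)
  if (r$num == 0) return(qp_zero(p$vars))
  cf <- rat_mul(p$coef, rat(rep(r$num, rat_len(p$coef)), rep(r$den, rat_len(p$coef))))
  qp_new(p$vars, p$E, cf)
}

qp_mul <- function(p, q) {
  if (!identical(p$vars, q$vars)) {
    vars <- union(p$vars, q$vars)
    p <- qp_align(p, vars); q <- qp_align(q, vars)
  }
  np <- nrow(p$E); nq <- nrow(q$E)
  if (np == 0 || nq == 0) return(qp_zero(p$vars))
  i <- rep(seq_len(np), each = nq)
  j <- rep(seq_len(nq), times = np)
  E <- p$E[i, , drop = FALSE] + q$E[j, , drop = FALSE]
  cf <- rat_mul(rat_slice(p$coef, i), rat_slice(q$coef, j))
  qp_new(p$vars, E, cf)
}

qp_pow <- function(p, n) {
  stopifnot(n == round(n), n >= 0)
  out <- qp_const(p$vars, 1)
  for (i in seq_len(n)) out <- qp_mul(out, p)
  out
}

qp_deriv <- function(p, var) {
  j <- match(var, p$vars)
  stopifnot(!is.na(j))
  keep <- p$E[, j] > 0
  if (!any(keep)) return(qp_zero(p$vars))
  E <- p$E[keep, , drop = FALSE]
  cf <- rat_mul(rat_slice(p$coef, keep), rat(E[, j]))
  E[, j] <- E[, j] - 1
  qp_new(p$vars, E, cf)
}

qp_total_degree <- function(p) if (nrow(p$E) == 0) -Inf else max(rowSums(p$E))

# numeric evaluation; A is a matrix with one row per point, columns in the
# order of p$vars (or a named vector for a single point)
qp_eval <- function(p, A) {
  if (is.null(dim(A))) A <- matrix(A, 1, dimnames = list(NULL, names(A)))
  if (!is.null(colnames(A)) && all(p$vars %in% colnames(A))) A <- A[, p$vars, drop = FALSE]
  stopifnot(ncol(A) == length(p$vars))
  out <- numeric(nrow(A))
  cf <- rat_as_numeric(p$coef)
  for (t in seq_len(nrow(p$E))) {
    v <- rep(cf[t], nrow(A))
    for (j in which(p$E[t, ] > 0)) v <- v * A[, j]^p$E[t, j]
    out <- out + v
  }
  out
}

# exact evaluation at a rational point (named list of rat scalars)
qp_eval_rat <- function(p, point) {
  out <- rat(0)
  for (t in seq_len(nrow(p$E))) {
    v <- rat_slice(p$coef, t)
    for (j in which(p$E[t, ] > 0))
      v <- rat_mul(v, rat_pow(point[[p$vars[j]]], p$E[t, j]))
    out <- rat_add(out, v)
  }
  out
}

# substitute exact rational values for a subset of the variables
qp_subs_rat <- function(p, values) {
  keep_vars <- setdiff(p$vars, names(values))
  out <- qp_zero(keep_vars)
  for (t in seq_len(nrow(p$E))) {
    v <- rat_slice(p$coef, t)
    for (nm in names(values)) {
      e <- p$E[t, match(nm, p$vars)]
      if (e > 0) v <- rat_mul(v, rat_pow(values[[nm]], e))
    }
    E <- matrix(p$E[t, match(keep_vars, p$vars)], 1)
    out <- qp_add(out, qp_new(keep_vars, E, v))
  }
  out
}

# content normalization: integer coprime coefficients, positive leading
# coefficient in the canonical term order; canonical form for deduplication
qp_normalize <- function(p) {
  if (qp_is_zero(p)) return(p)
  den_lcm <- 1
  for (d in p$coef$den) den_lcm <- rat_guard(den_lcm * d / gcd_int(den_lcm, d))
  num <- rat_guard(p$coef$num * (den_lcm / p$coef$den))
  g <- 0
  for (v in num) g <- gcd_int(g, v)
  num <- num / g
  if (num[1] < 0) num <- -num
  qp_new(p$vars, p$E, rat(num))
}

# are p and q unit (nonzero rational) multiples of each other?
qp_proportional <- function(p, q) {
  if (!identical(sort(p$vars), sort(q$vars))) {
    vars <- union(p$vars, q$vars)
    p <- qp_align(p, vars); q <- qp_align(q, vars)
  } else if (!identical(p$vars, q$vars)) q <- qp_align(q, p$vars)
  identical(qp_key(qp_normalize(p)), qp_key(qp_normalize(q)))
}

qp_string <- function(p, power_op = "^") {
  if (qp_is_zero(p)) return("0")
  terms <- character(nrow(p$E))
  for (t in seq_len(nrow(p$E))) {
    parts <- character(0)
    cf <- rat_slice(p$coef, t)
    for (j in which(p$E[t, ] > 0)) {
      e <- p$E[t, j]
      parts <- c(parts, if (e == 1) p$vars[j] else paste0(p$vars[j], power_op, format_int(e)))
    }
    cs <- rat_format(rat_abs(cf))
    body <- if (length(parts) == 0) cs
            else if (cs == "1") paste(parts, collapse = "*")
            else paste(c(cs, parts), collapse = "*")
    terms[t] <- paste0(if (cf$num < 0) " - " else if (t > 1) " + " else "", body)
  }
  paste(terms, collapse = "")
}

qp_key <- function(p) qp_string(p)

#' @export
print.qpoly <- function(x, ...) {
  cat(qp_string(x), "\n")
  invisible(x)
}

#' @export
format.qpoly <- function(x, ...) qp_string(x)
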