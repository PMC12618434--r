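# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: brute-force determinant expansion, finite
# differences, dense scans.

# determinant of a list-matrix of qpoly by cofactor expansion
qp_det <- function(M) {
  n <- dim(M)[1]
  if (n == 1) return(M[[1, 1]])
  acc <- NULL
  for (j in seq_len(n)) {
    sub <- M[-1, -j, drop = FALSE]
    term <- stabscape:::qp_mul(M[[1, j]], qp_det(sub))
    if (j %% 2 == 0) term <- stabscape:::qp_neg(term)
    acc <- if (is.null(acc)) term else stabscape:::qp_add(acc, term)
  }
  acc
}

# Sylvester-matrix resultant of univariate (in `x`) polynomials whose
# coefficients are qpoly in the parameters
sylvester_resultant <- function(f_coeffs, g_coeffs, vars) {
  # coefficients descending in x
  m <- length(f_coeffs) - 1; n <- length(g_coeffs) - 1
  N <- m + n
  zero <- stabscape:::qp_zero(vars)
  M <- vector("list", N * N); dim(M) <- c(N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) M[[i, j]] <- zero
  for (i in seq_len(n)) for (j in seq_along(f_coeffs))
    M[[i, i + j - 1]] <- f_coeffs[[j]]
  for (i in seq_len(m)) for (j in seq_along(g_coeffs))
    M[[n + i, i + j - 1]] <- g_coeffs[[j]]
  qp_det(M)
}

# central finite-difference Jacobian of a system's rates
fd_jacobian <- function(sys, point, h = 1e-6) {
  n <- length(sys$variables)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    up <- point; up[sys$variables[j]] <- up[sys$variables[j]] + h
    dn <- point; dn[sys$variables[j]] <- dn[sys$variables[j]] - h
    Aup <- matrix(up, 1, dimnames = list(NULL, names(up)))
    Adn <- matrix(dn, 1, dimnames = list(NULL, names(dn)))
    for (i in seq_len(n))
      J[i, j] <- (stabscape:::qrf_eval(sys$rates[[i]], Aup) -
                  stabscape:::qrf_eval(sys$rates[[i]], Adn)) / (2 * h)
  }
  J
}

# monic characteristic polynomial coefficients by Vandermonde interpolation
# of det(lambda I - J) -- independent of the minors-based implementation
charpoly_interp <- function(J) {
  n <- nrow(J)
  lam <- 0:n
  vals <- vapply(lam, function(l) det(l * diag(n) - J), 0)
  V <- outer(lam, 0:n, `^`)
  as.vector(solve(V, vals))  # ascending c_0..c_n
}

# count local extrema and saddles of a routing function by dense grid scan
grid_extrema_scan <- function(rf, box = c(0.05, 10), res = 400) {
  xs <- seq(box[1], box[2], length.out = res)
  G <- as.matrix(expand.grid(xs, xs))
  V <- matrix(rf_value(rf, G), res, res)
  inner <- 2:(res - 1)
  n_ext <- 0
  for (i in inner) for (j in inner) {
    nb <- c(V[i - 1, j], V[i + 1, j], V[i, j - 1], V[i, j + 1],
            V[i - 1, j - 1], V[i - 1, j + 1], V[i + 1, j - 1], V[i + 1, j + 1])
    if (all(V[i, j] > nb) || all(V[i, j] < nb)) n_ext <- n_ext + 1
  }
  n_ext
}

lc_printed_factors <- function() {
  # the competition-colonization model's seven boundary factors
  vars <- c("beta_y", "beta_z", "gamma_y", "gamma_z")
  lapply(c(
    "beta_y - gamma_y",
    "beta_z - gamma_z",
    "beta_y - beta_z - gamma_y + gamma_z",
    "beta_y + beta_z - gamma_y - gamma_z",
    "beta_z*gamma_y - beta_y*gamma_z",
    "beta_y^2 - beta_y*gamma_y - beta_z*gamma_y + beta_y*gamma_z",
    "2*beta_y^2 - 2*beta_y*gamma_y - beta_z*gamma_y + beta_y*gamma_z"
  ), stabscape:::parse_poly, vars = vars)
}
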