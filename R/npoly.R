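# Numeric (double/complex coefficient) views of sparse polynomials, used by
# the steady-state and critical-point solvers after parameters are fixed.

np_from_qp <- function(p, values = NULL) {
  # values: named numeric vector of variables to substitute
  E <- p$E
  coef <- rat_as_numeric(p$coef)
  if (!is.null(values) && length(values)) {
    sub_idx <- match(names(values), p$vars)
    stopifnot(!anyNA(sub_idx))
    for (s in seq_along(sub_idx)) {
      j <- sub_idx[s]
      coef <- coef * values[s]^E[, j]
    }
    keep <- setdiff(seq_along(p$vars), sub_idx)
    E <- E[, keep, drop = FALSE]
    vars <- p$vars[keep]
  } else vars <- p$vars
  np_canon(list(vars = vars, E = E, coef = coef))
}

np_canon <- function(p) {
  if (nrow(p$E)) {
    key <- apply(p$E, 1, paste, collapse = ",")
    if (anyDuplicated(key)) {
      uk <- unique(key)
      E <- p$E[match(uk, key), , drop = FALSE]
      coef <- vapply(uk, function(k) sum(p$coef[key == k]), p$coef[1] * 0)
      p$E <- E; p$coef <- coef
    }
    keep <- Mod(p$coef) > 0
    p$E <- p$E[keep, , drop = FALSE]
    p$coef <- p$coef[keep]
  }
  p
}

np_is_const <- function(p) nrow(p$E) == 0 || all(p$E == 0)

np_const_val <- function(p) if (nrow(p$E) == 0) 0 else p$coef[which(rowSums(p$E) == 0)[1]]

np_eval <- function(p, A) {
  if (is.null(dim(A))) A <- matrix(A, 1)
  out <- if (is.complex(p$coef) || is.complex(A)) complex(real = numeric(nrow(A)))
         else numeric(nrow(A))
  for (t in seq_len(nrow(p$E))) {
    v <- rep(p$coef[t], nrow(A))
    for (j in which(p$E[t, ] > 0)) v <- v * A[, j]^p$E[t, j]
    out <- out + v
  }
  out
}

# substitute numeric/complex values for a subset of vars
np_subs <- function(p, values) {
  idx <- match(names(values), p$vars)
  stopifnot(!anyNA(idx))
  coef <- p$coef
  for (s in seq_along(idx)) coef <- coef * values[[s]]^p$E[, idx[s]]
  keep <- setdiff(seq_along(p$vars), idx)
  np_canon(list(vars = p$vars[keep], E = p$E[, keep, drop = FALSE], coef = coef))
}

np_nvars_used <- function(p) {
  if (nrow(p$E) == 0) return(character(0))
  p$vars[colSums(p$E) > 0]
}

# univariate coefficient vector (ascending powers) when p uses a single var
np_uni_coeffs <- function(p, var) {
  j <- match(var, p$vars)
  d <- if (nrow(p$E)) max(p$E[, j]) else 0
  cf <- rep(if (is.complex(p$coef)) 0 + 0i else 0, d + 1)
  for (t in seq_len(nrow(p$E))) cf[p$E[t, j] + 1] <- cf[p$E[t, j] + 1] + p$coef[t]
  cf
}
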