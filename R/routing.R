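# Routing functions: bounded rational functions that vanish exactly on a
# hypersurface arrangement (and, in positive-orthant mode, on the coordinate
# hyperplanes), whose critical points catalogue the connected components of
# the complement.

#' Build a routing function for a hypersurface arrangement
#'
#' Constructs
#' \deqn{r_c(a) = \frac{g_1(a) \cdots g_m(a) \prod_i a_i}
#'                    {(1 + \sum_i (a_i - c_i)^2)^D}}
#' with a generic center \eqn{c} and an exponent \eqn{D} large enough that
#' \eqn{2D} exceeds the numerator degree, so \eqn{r_c \to 0} at infinity.
#' The coordinate product is included in positive-orthant mode unless the
#' arrangement already contains the coordinate hyperplanes.
#'
#' @param arr a [hypersurface_arrangement()].
#' @param center optional center `c` (numeric or strings of exact rationals);
#'   drawn uniformly from \eqn{(0.5, 1.5)^k} under `seed` when omitted.
#' @param seed integer seed for the center draw.
#' @param restrict_positive confine attention to the open positive orthant
#'   by multiplying the coordinates into the numerator.
#' @param D optional override of the denominator exponent.
#' @return object of class `routing_function`.
#' @export
build_routing_function <- function(arr, center = NULL, seed = 1L,
                                   restrict_positive = TRUE, D = NULL) {
  stopifnot(inherits(arr, "hypersurface_arrangement"))
  pars <- arr$parameters
  k <- length(pars)
  factors <- lapply(arr$polys, qp_align, vars = pars)
  is_coord <- arr$is_coordinate
  if (restrict_positive) {
    # a non-coordinate factor whose (sign-normalized) coefficients are all
    # positive cannot vanish on the open positive orthant: it contributes no
    # region wall there and is omitted from the numerator
    definite <- vapply(factors, function(p) {
      p <- qp_normalize(p)
      all(p$coef$num > 0)
    }, TRUE) & !is_coord
    factors <- factors[!definite]
    is_coord <- is_coord[!definite]
    have <- vapply(seq_along(factors), function(i) {
      if (!is_coord[i]) return("")
      p <- factors[[i]]
      p$vars[p$E[1, ] == 1]
    }, "")
    for (a in setdiff(pars, have)) factors <- c(factors, list(qp_var(pars, a)))
  }
  if (!length(factors)) stop("empty arrangement without positive-orthant restriction",
                             call. = FALSE)
  deg_num <- sum(vapply(factors, qp_total_degree, 0))
  if (is.null(D)) D <- floor(deg_num / 2) + 1
  if (2 * D <= deg_num) stop("D too small: need 2D > ", deg_num, call. = FALSE)
  if (is.null(center)) {
    set.seed(seed)
    center <- rat(round(stats::runif(k, 0.5, 1.5) * 10000), 10000)
  } else if (is.numeric(center)) {
    center <- rat(round(center * 10000), 10000)
  } else if (is.character(center)) {
    parsed <- lapply(center, rat_parse)
    center <- rat(vapply(parsed, function(r) r$num, 0),
                  vapply(parsed, function(r) r$den, 0))
  }
  stopifnot(inherits(center, "rat"), rat_len(center) == k)
  fcache <- lapply(factors, function(p) {
    grad <- lapply(pars, function(v) qp_deriv(p, v))
    hess <- vector("list", k * k); dim(hess) <- c(k, k)
    for (i in seq_len(k)) for (j in i:k) {
      hess[[i, j]] <- qp_deriv(grad[[i]], pars[j])
      hess[[j, i]] <- hess[[i, j]]
    }
    out <- list(val = np_from_qp(p),
                grad = lapply(grad, np_from_qp),
                hess = lapply(hess, np_from_qp),
                degree = qp_total_degree(p))
    # scale each factor to unit leading magnitude: multiplies r by a positive
    # constant, leaving critical points, indices and flows unchanged, but
    # keeps high-degree products inside double dynamic range
    s <- max(abs(out$val$coef))
    if (is.finite(s) && s > 0) {
      out$val$coef <- out$val$coef / s
      out$grad <- lapply(out$grad, function(g) { g$coef <- g$coef / s; g })
      out$hess <- lapply(out$hess, function(h) { h$coef <- h$coef / s; h })
    }
    out
  })
  structure(list(arr = arr, factors = factors, fcache = fcache,
                 parameters = pars, k = k,
                 center = center, center_num = rat_as_numeric(center),
                 D = D, deg_num = deg_num, seed = seed,
                 restrict_positive = restrict_positive),
            class = "routing_function")
}

#' @export
print.routing_function <- function(x, ...) {
  cat("routing function in", x$k, "parameters:",
      length(x$factors), "numerator factors, numerator degree", x$deg_num,
      ", denominator exponent D =", x$D, "\n")
  cat("  center c = (", paste(signif(x$center_num, 6), collapse = ", "), ")\n")
  invisible(x)
}

# shared power tables: pw[[j]][, e+1] = A[, j]^e, reused by every factor
rf_power_tables <- function(rf, A) {
  maxd <- max(vapply(rf$fcache, function(f) f$degree, 0), 1)
  lapply(seq_len(rf$k), function(j) {
    pw <- matrix(1, nrow(A), maxd + 1)
    for (e in seq_len(maxd)) pw[, e + 1] <- pw[, e] * A[, j]
    pw
  })
}

np_eval_pw <- function(p, pw, n) {
  out <- numeric(n)
  for (t in seq_len(nrow(p$E))) {
    v <- rep(p$coef[t], n)
    for (j in which(p$E[t, ] > 0)) v <- v * pw[[j]][, p$E[t, j] + 1]
    out <- out + v
  }
  out
}

# numerator value/gradient/Hessian at the rows of A, by product-rule
# accumulation over the (low-degree) factors; vectorized over points
rf_num_eval <- function(rf, A, hessian = TRUE) {
  if (is.null(dim(A))) A <- matrix(A, 1)
  n <- nrow(A); k <- rf$k
  pw <- rf_power_tables(rf, A)
  P <- rep(1, n)
  G <- matrix(0, n, k)
  H <- if (hessian) array(0, c(n, k, k)) else NULL
  for (f in rf$fcache) {
    fv <- np_eval_pw(f$val, pw, n)
    fg <- matrix(0, n, k)
    for (j in seq_len(k)) if (nrow(f$grad[[j]]$E)) fg[, j] <- np_eval_pw(f$grad[[j]], pw, n)
    if (hessian) {
      fh <- array(0, c(n, k, k))
      for (i in seq_len(k)) for (j in i:k) {
        hp <- f$hess[[i + (j - 1) * k]]
        if (nrow(hp$E)) { v <- np_eval_pw(hp, pw, n); fh[, i, j] <- v; fh[, j, i] <- v }
      }
      Hn <- array(0, c(n, k, k))
      for (i in seq_len(k)) for (j in seq_len(k))
        Hn[, i, j] <- P * fh[, i, j] + fv * H[, i, j] +
                      G[, i] * fg[, j] + fg[, i] * G[, j]
      H <- Hn
    }
    G <- P * fg + fv * G
    P <- P * fv
  }
  list(val = P, grad = G, hess = H)
}

rf_den <- function(rf, A) {
  if (is.null(dim(A))) A <- matrix(A, 1)
  1 + rowSums(sweep(A, 2, rf$center_num)^2)
}

#' Evaluate a routing function
#' @param rf a `routing_function`.
#' @param A matrix of points (rows) or a single point vector.
#' @return numeric vector of values.
#' @export
rf_value <- function(rf, A) {
  if (is.null(dim(A))) A <- matrix(A, 1)
  rf_num_eval(rf, A, hessian = FALSE)$val / rf_den(rf, A)^rf$D
}

# gradient of r itself
rf_grad <- function(rf, A) {
  if (is.null(dim(A))) A <- matrix(A, 1)
  ne <- rf_num_eval(rf, A, hessian = FALSE)
  dd <- rf_den(rf, A)
  amc <- sweep(A, 2, rf$center_num)
  (dd * ne$grad - 2 * rf$D * ne$val * amc) / dd^(rf$D + 1)
}

# cleared-denominator gradient system p_i and its Jacobian
rf_grad_system <- function(rf, A, jacobian = TRUE) {
  if (is.null(dim(A))) A <- matrix(A, 1)
  n <- nrow(A); k <- rf$k; D <- rf$D
  ne <- rf_num_eval(rf, A, hessian = jacobian)
  dd <- rf_den(rf, A)
  amc <- sweep(A, 2, rf$center_num)
  p <- dd * ne$grad - 2 * D * ne$val * amc
  scale <- abs(dd) * sqrt(rowSums(ne$grad^2)) + 2 * D * abs(ne$val) * sqrt(rowSums(amc^2)) + 1
  if (!jacobian) return(list(p = p, scale = scale, num = ne$val))
  Jp <- array(0, c(n, k, k))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    Jp[, i, j] <- 2 * amc[, j] * ne$grad[, i] + dd * ne$hess[, i, j] -
                  2 * D * amc[, i] * ne$grad[, j] -
                  2 * D * ne$val * (i == j)
  }
  list(p = p, Jp = Jp, scale = scale, num = ne$val, grad_num = ne$grad, den = dd)
}

# full Hessian of r at the rows of A
rf_hess <- function(rf, A) {
  if (is.null(dim(A))) A <- matrix(A, 1)
  n <- nrow(A); k <- rf$k; D <- rf$D
  ne <- rf_num_eval(rf, A, hessian = TRUE)
  dd <- rf_den(rf, A)
  amc <- sweep(A, 2, rf$center_num)
  out <- array(0, c(n, k, k))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out[, i, j] <- ne$hess[, i, j] / dd^D -
      D / dd^(D + 1) * (ne$grad[, i] * 2 * amc[, j] + 2 * amc[, i] * ne$grad[, j] +
                        ne$val * 2 * (i == j)) +
      D * (D + 1) * ne$val / dd^(D + 2) * 4 * amc[, i] * amc[, j]
  }
  out
}

# batched linear solve: M is n x k x k, b is n x k; Gaussian elimination
# with partial pivoting, vectorized across the n systems
batch_solve <- function(M, b) {
  n <- dim(M)[1]; k <- dim(M)[2]
  if (k == 1) return(b / M[, 1, 1])
  for (j in seq_len(k - 1)) {
    # partial pivot among rows j..k
    sub <- abs(matrix(M[, j:k, j], n))
    piv <- max.col(sub, ties.method = "first") + j - 1
    need <- piv != j
    if (any(need)) {
      idx <- which(need)
      for (col in seq_len(k)) {
        tmp <- M[cbind(idx, piv[idx], col)]
        M[cbind(idx, piv[idx], col)] <- M[cbind(idx, j, col)]
        M[cbind(idx, j, col)] <- tmp
      }
      tmp <- b[cbind(idx, piv[idx])]
      b[cbind(idx, piv[idx])] <- b[cbind(idx, j)]
      b[cbind(idx, j)] <- tmp
    }
    for (i in (j + 1):k) {
      f <- M[, i, j] / M[, j, j]
      for (col in j:k) M[, i, col] <- M[, i, col] - f * M[, j, col]
      b[, i] <- b[, i] - f * b[, j]
    }
  }
  x <- matrix(0, n, k)
  for (i in k:1) {
    acc <- b[, i]
    if (i < k) for (col in (i + 1):k) acc <- acc - M[, i, col] * x[, col]
    x[, i] <- acc / M[, i, i]
  }
  x
}

# batched Newton solve of the cleared gradient system from start rows
rf_newton <- function(rf, A, iters = 50, clip = 0.5) {
  k <- rf$k
  active <- seq_len(nrow(A))
  for (it in seq_len(iters)) {
    if (!length(active)) break
    Aa <- A[active, , drop = FALSE]
    gs <- rf_grad_system(rf, Aa)
    step <- batch_solve(gs$Jp, gs$p)
    step[!is.finite(step)] <- NA
    step <- pmax(pmin(step, clip), -clip)
    Aa <- Aa - step
    bad <- !is.finite(rowSums(Aa)) | rowSums(abs(Aa)) > 1e6
    Aa[bad, ] <- NA
    A[active, ] <- Aa
    moved <- is.finite(rowSums(step)) &
      sqrt(rowSums(step^2)) > 1e-14 * (1 + sqrt(rowSums(Aa^2)))
    moved[is.na(moved)] <- FALSE
    active <- active[moved & !bad]
  }
  A
}

# residual-accept, boundary-exclude and dedupe a candidate matrix
rf_accept <- function(rf, A, pos_tol = 1e-9, res_tol = 1e-9, dedup_tol = 1e-8) {
  keep <- is.finite(rowSums(A))
  A <- A[keep, , drop = FALSE]
  if (!nrow(A)) return(A)
  gs <- rf_grad_system(rf, A, jacobian = FALSE)
  res <- sqrt(rowSums(gs$p^2)) / gs$scale
  ok <- res < res_tol
  if (rf$restrict_positive) ok <- ok & apply(A, 1, function(a) all(a > pos_tol))
  # genuine criticality of r itself: points converging onto the singular
  # locus of the arrangement (where N and grad N vanish together) solve the
  # cleared system but are not critical points of r
  v <- rf_value(rf, A)
  gr <- rf_grad(rf, A)
  relcrit <- sqrt(rowSums(gr^2)) * (1 + sqrt(rowSums(A^2))) / pmax(abs(v), 1e-300)
  ok <- ok & relcrit < 1e-6
  # boundary exclusion: first-order relative distance to each factor's zero
  # set, |f| / (||grad f|| (1 + ||a||)); a point is on the arrangement when
  # this is negligible for some factor
  nr <- 1 + sqrt(rowSums(A^2))
  drel <- vapply(rf$fcache, function(f) {
    fv <- abs(np_eval(f$val, A))
    gn <- sqrt(Reduce(`+`, lapply(f$grad, function(g)
      if (nrow(g$E)) np_eval(g, A)^2 else numeric(nrow(A)))))
    fv / ((gn + fv / nr + 1e-300) * nr)
  }, numeric(nrow(A)))
  if (is.null(dim(drel))) drel <- matrix(drel, nrow(A))
  on_b <- apply(drel, 1, min) < 1e-9
  ok <- ok & !on_b
  A <- A[ok, , drop = FALSE]
  if (nrow(A) < 2) return(A)
  # coarse collapse of numerically identical rows, then pairwise pass
  key <- apply(signif(A, 7), 1, paste, collapse = ",")
  A <- A[!duplicated(key), , drop = FALSE]
  if (nrow(A) < 2) return(A)
  keep <- rep(TRUE, nrow(A))
  for (i in 2:nrow(A)) {
    for (j in seq_len(i - 1)) {
      if (keep[j] && sqrt(sum((A[i, ] - A[j, ])^2)) <
          dedup_tol * (1 + sqrt(sum(A[j, ]^2)))) { keep[i] <- FALSE; break }
    }
  }
  A[keep, , drop = FALSE]
}

#' Critical points of a routing function
#'
#' Finds the real solutions of the cleared-denominator gradient system
#' \eqn{(1 + \|a - c\|^2)\,\partial_i N - 2 D N (a_i - c_i) = 0}, excluding
#' points on the arrangement or the coordinate hyperplanes. For one or two
#' parameters of modest degree the solve is deterministic (resultants with
#' exact real-root isolation, then Newton pairing); otherwise a seeded
#' multistart Newton search over batches of scrambled starts runs until the
#' point set stabilizes (two consecutive batches finding nothing new).
#'
#' @param rf a `routing_function`.
#' @param method `"auto"`, `"resultant"` or `"multistart"`.
#' @param box search box upper bound(s) for multistart (lower bound is 0 in
#'   positive-orthant mode).
#' @param seed seed for multistart batches.
#' @param batches,batch_size multistart budget.
#' @return matrix of critical points (one row each).
#' @export
critical_points <- function(rf, method = c("auto", "resultant", "multistart"),
                            box = NULL, seed = 1L, batches = 12,
                            batch_size = NULL) {
  method <- match.arg(method)
  k <- rf$k
  if (method == "auto")
    method <- if (k == 1 || (k == 2 && rf$deg_num <= 8)) "resultant" else "multistart"
  if (method == "resultant" && k > 2)
    stop("resultant path requires k <= 2", call. = FALSE)
  if (method == "resultant") cp_resultant(rf) else
    cp_multistart(rf, box = box, seed = seed, batches = batches,
                  batch_size = batch_size)
}

# expanded numerator as qpoly (only used on low-degree deterministic path)
rf_num_expanded <- function(rf) {
  N <- qp_const(rf$parameters, 1)
  for (p in rf$factors) N <- qp_mul(N, p)
  N
}

rf_grad_polys <- function(rf) {
  # exact cleared gradient system as qpoly (rational center)
  pars <- rf$parameters
  N <- rf_num_expanded(rf)
  den <- qp_const(pars, 1)
  for (i in seq_len(rf$k)) {
    ai <- qp_sub(qp_var(pars, pars[i]), qp_const(pars, rat_slice(rf$center, i)))
    den <- qp_add(den, qp_mul(ai, ai))
  }
  lapply(seq_len(rf$k), function(i) {
    ai <- qp_sub(qp_var(pars, pars[i]), qp_const(pars, rat_slice(rf$center, i)))
    qp_sub(qp_mul(den, qp_deriv(N, pars[i])),
           qp_scale(qp_mul(N, ai), rat(2 * rf$D)))
  })
}

cp_resultant <- function(rf) {
  gp <- rf_grad_polys(rf)
  if (rf$k == 1) {
    cfs <- np_uni_coeffs(np_from_qp(gp[[1]]), rf$parameters[1])
    roots <- polyroot(cfs)
    A <- matrix(Re(roots[abs(Im(roots)) < 1e-7 * (1 + abs(roots))]), ncol = 1)
    A <- rf_newton(rf, A, iters = 10, clip = 10)
    return(label_cp(rf, rf_accept(rf, A)))
  }
  res <- cas_one(list(op = "real_roots_biv",
                      p1 = qp_string(gp[[1]], power_op = "**"),
                      p2 = qp_string(gp[[2]], power_op = "**"),
                      vars = as.list(rf$parameters)))
  if (isTRUE(res$common_factor))
    stop("gradient system is degenerate (shared factor); redraw the center",
         call. = FALSE)
  r1 <- as.numeric(unlist(res$roots1)); r2 <- as.numeric(unlist(res$roots2))
  if (!length(r1) || !length(r2))
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, rf$parameters)))
  cand <- as.matrix(expand.grid(r1, r2))
  pol <- rf_newton(rf, cand, iters = 30, clip = 1)
  near <- is.finite(rowSums(pol)) &
    abs(pol[, 1] - cand[, 1]) < 1e-4 * (1 + abs(cand[, 1])) &
    abs(pol[, 2] - cand[, 2]) < 1e-4 * (1 + abs(cand[, 2]))
  label_cp(rf, rf_accept(rf, pol[near, , drop = FALSE]))
}

cp_multistart <- function(rf, box = NULL, seed = 1L, batches = 14,
                          batch_size = NULL) {
  k <- rf$k
  if (is.null(box)) box <- rep(8, k)
  if (length(box) == 1) box <- rep(box, k)
  if (is.null(batch_size)) batch_size <- 1200 * k
  found <- matrix(numeric(0), 0, k)
  quiet <- 0
  for (b in seq_len(batches)) {
    set.seed(seed * 1000 + b)
    if (b == 1) {
      # stratified (jittered-grid) first batch for uniform basin coverage
      g <- max(2, floor(batch_size^(1 / k)))
      cells <- as.matrix(expand.grid(rep(list(seq_len(g) - 1), k)))
      A0 <- (cells + matrix(stats::runif(nrow(cells) * k), nrow(cells), k)) / g
    } else {
      A0 <- matrix(stats::runif(batch_size * k, 1e-3, 1), batch_size, k)
    }
    A0 <- sweep(A0, 2, box, `*`)
    A <- rf_newton(rf, A0, iters = 38, clip = 0.75)
    A <- rf_accept(rf, A)
    before <- nrow(found)
    found <- rf_accept(rf, rbind(found, A))
    if (nrow(found) == before) quiet <- quiet + 1 else quiet <- 0
    if (quiet >= 2 && b >= 3) break
  }
  label_cp(rf, found)
}

label_cp <- function(rf, A) {
  colnames(A) <- rf$parameters
  # deterministic order: by value magnitude descending, then coords
  if (nrow(A) > 1) {
    v <- abs(rf_value(rf, A))
    A <- A[do.call(order, c(list(-v), lapply(seq_len(ncol(A)), function(j) A[, j]))), ,
           drop = FALSE]
  }
  A
}

#' Classify a critical point into a routing point
#'
#' Evaluates the routing function's value, gradient residual and Hessian at
#' the point, computes the eigendecomposition, and attaches the index (the
#' number of Hessian eigenvalues sharing the sign of the value) and the
#' unstable eigenvector directions.
#'
#' @param rf a `routing_function`.
#' @param point numeric coordinate vector.
#' @param degen_tol relative eigenvalue tolerance below which the point is
#'   flagged degenerate (genericity failure).
#' @return object of class `routing_point`.
#' @export
classify <- function(rf, point, degen_tol = 1e-7) {
  A <- matrix(point, 1)
  val <- rf_value(rf, A)
  g <- rf_grad(rf, A)
  H <- rf_hess(rf, A)[1, , , drop = TRUE]
  if (rf$k == 1) H <- matrix(H, 1, 1)
  eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
  srad <- max(abs(eg$values))
  degenerate <- any(abs(eg$values) < degen_tol * srad) || srad == 0
  idx <- sum(sign(eg$values) == sign(val))
  unstable <- which(sign(eg$values) == sign(val))
  dirs <- lapply(unstable, function(j) eg$vectors[, j])
  structure(list(coords = drop(A), value = val,
                 grad_norm = sqrt(sum(g^2)),
                 hess_eigenvalues = eg$values,
                 hess_eigenvectors = eg$vectors,
                 index = idx, unstable_dirs = dirs,
                 degenerate = degenerate),
            class = "routing_point")
}

#' @export
print.routing_point <- function(x, ...) {
  cat(sprintf("routing point (%s): r = %.6g, index %d%s\n",
              paste(signif(x$coords, 6), collapse = ", "),
              x$value, x$index,
              if (x$degenerate) " [DEGENERATE]" else ""))
  invisible(x)
}

#' Check the genericity conditions for a set of routing points
#'
#' Verifies nondegeneracy of every Hessian (condition: each critical point
#' non-degenerate) and pairwise distinctness of the nonzero critical values
#' (condition: at most one critical point per level set). Finiteness is
#' certified by the solver. A failing report signals that the center `c`
#' should be redrawn.
#'
#' @param rf a `routing_function`.
#' @param points list of `routing_point`s.
#' @param value_tol relative tolerance for value collisions.
#' @return list with `pass` and a character vector `reasons`.
#' @export
genericity_check <- function(rf, points, value_tol = 1e-6) {
  reasons <- character(0)
  if (length(points)) {
    if (any(vapply(points, `[[`, TRUE, "degenerate")))
      reasons <- c(reasons, "degenerate critical point (Hessian eigenvalue near 0)")
    vals <- vapply(points, `[[`, 0, "value")
    if (length(vals) > 1) {
      sv <- sort(vals)
      gaps <- diff(sv) / pmax(abs(sv[-1]), abs(sv[-length(sv)]), 1e-300)
      if (any(gaps < value_tol))
        reasons <- c(reasons, "duplicate critical values")
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Compute genericity-checked routing points of an arrangement
#'
#' Builds a routing function (drawing the center from `seed`), solves for
#' its critical points and classifies them; if a genericity condition fails
#' the center is redrawn (up to `max_draws` seeds, each logged).
#'
#' @param arr a [hypersurface_arrangement()].
#' @param seed first center seed.
#' @param max_draws number of centers to try.
#' @inheritParams critical_points
#' @param restrict_positive positive-orthant mode (see
#'   [build_routing_function()]).
#' @return list with `rf` (the accepted routing function), `points` (list of
#'   `routing_point`s) and `seeds_tried`.
#' @export
routing_points <- function(arr, seed = 1L, max_draws = 5,
                           method = "auto", box = NULL,
                           restrict_positive = TRUE, grid_assist = FALSE,
                           batches = 14, batch_size = NULL) {
  tried <- integer(0)
  for (s in seed + 1000L * (seq_len(max_draws) - 1L)) {
    tried <- c(tried, s)
    rf <- build_routing_function(arr, seed = s, restrict_positive = restrict_positive)
    A <- critical_points(rf, method = method, box = box, seed = s,
                         batches = batches, batch_size = batch_size)
    if (grid_assist && rf$k == 2) {
      # ascend from sign-grid region representatives so that routing points
      # with very small Newton basins (tiny regions) are still discovered
      bx <- if (is.null(box)) 10 else max(box)
      gl <- grid_components(arr, box = c(1e-4, bx), resolution = 360)
      asc <- ascend_batch(rf, gl$representatives, max_steps = 400)
      extra <- asc$X[asc$started, , drop = FALSE]
      if (nrow(extra)) {
        extra <- rf_newton(rf, extra, iters = 30, clip = 0.5)
        A <- rf_accept(rf, rbind(A, extra))
        A <- label_cp(rf, A)
      }
    }
    pts <- lapply(seq_len(nrow(A)), function(i) classify(rf, A[i, ]))
    chk <- genericity_check(rf, pts)
    if (chk$pass)
      return(list(rf = rf, points = pts, seeds_tried = tried))
    message("genericity failed for center seed ", s, " (",
            paste(chk$reasons, collapse = "; "), "); redrawing center")
  }
  stop("genericity failed for ", max_draws, " centers (seeds ",
       paste(tried, collapse = ", "), ")", call. = FALSE)
}
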