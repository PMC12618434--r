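# Independent component-counting oracles and built-in fixtures.
#
# The grid oracle flood-fills a sign-vector labeling of a box: two cells are
# joined only when they are axis-adjacent with identical sign vectors over
# the arrangement polynomials. The roadmap oracle joins sampled points whose
# connecting segment keeps a constant sign vector; for homogeneous
# arrangements (all boundary polynomials are forms, so the positive orthant
# is a cone over a simplex slice) it samples the simplex, which avoids the
# unboundedly thin wedges near the origin that defeat any fixed-resolution
# grid.

#' Grid flood-fill component count of an arrangement complement
#'
#' @param arr a [hypersurface_arrangement()].
#' @param box numeric `c(lo, hi)` applied to every axis, or a `2 x k` matrix.
#' @param resolution cells per axis (>= 20).
#' @param stabilize require the count to be unchanged under one resolution
#'   doubling before reporting (up to 3 doublings, else flagged
#'   inconclusive).
#' @return object of class `grid_labeling`: `count`, `representatives`
#'   (matrix, one interior representative per component), `resolution`,
#'   `stable`, plus per-cell internals.
#' @export
grid_components <- function(arr, box = c(0, 10), resolution = 100,
                            stabilize = FALSE) {
  k <- length(arr$parameters)
  stopifnot(k >= 1, k <= 4, resolution >= 20)
  if (!stabilize) return(grid_once(arr, box, resolution))
  g1 <- grid_once(arr, box, resolution)
  for (d in 1:3) {
    g2 <- grid_once(arr, box, resolution * 2^d)
    if (g2$count == g1$count) {
      g2$stable <- TRUE
      return(g2)
    }
    g1 <- g2
  }
  g1$stable <- FALSE
  g1
}


# integer-free sign-vector encoding: exact in doubles up to 33 polynomials,
# string keys beyond
sign_code <- function(S) {
  if (ncol(S) == 0) return(rep(0, nrow(S)))
  if (ncol(S) <= 33) {
    code <- numeric(nrow(S))
    for (j in seq_len(ncol(S))) code <- code * 3 + (S[, j] + 1)
    code
  } else {
    key <- apply(S, 1, paste, collapse = "")
    match(key, unique(key))
  }
}

grid_once <- function(arr, box, resolution) {
  k <- length(arr$parameters)
  if (is.null(dim(box))) box <- matrix(rep(box, k), 2)
  axes <- lapply(seq_len(k), function(j)
    box[1, j] + (seq_len(resolution) - 0.5) * (box[2, j] - box[1, j]) / resolution)
  G <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(G) <- arr$parameters
  V <- arr_eval(arr, G)
  if (is.null(dim(V))) V <- matrix(V, nrow(G))
  S <- sign(V)
  ok <- rowSums(S == 0) == 0
  code <- sign_code(S)
  dims <- rep(resolution, k)
  idx <- array(seq_len(nrow(G)), dims)
  from <- to <- integer(0)
  for (ax in seq_len(k)) {
    i1 <- slice_idx(idx, ax, 1:(resolution - 1))
    i2 <- slice_idx(idx, ax, 2:resolution)
    m <- code[i1] == code[i2] & ok[i1] & ok[i2]
    from <- c(from, i1[m]); to <- c(to, i2[m])
  }
  keep <- which(ok)
  remap <- integer(nrow(G)); remap[keep] <- seq_along(keep)
  g <- igraph::make_graph(edges = c(rbind(remap[from], remap[to])), n = length(keep),
                          directed = FALSE)
  cl <- igraph::components(g)
  # interior guard: representative cells must not border a sign change
  interior <- rep(TRUE, nrow(G))
  for (ax in seq_len(k)) {
    i1 <- slice_idx(idx, ax, 1:(resolution - 1))
    i2 <- slice_idx(idx, ax, 2:resolution)
    diffm <- code[i1] != code[i2] | !ok[i1] | !ok[i2]
    interior[i1[diffm]] <- FALSE
    interior[i2[diffm]] <- FALSE
  }
  depth <- if (ncol(V)) apply(sweep(abs(V), 2, colMeans(abs(V)) + 1e-300, "/"), 1, min)
           else rep(1, nrow(G))
  reps <- matrix(NA_real_, cl$no, k, dimnames = list(NULL, arr$parameters))
  for (cc in seq_len(cl$no)) {
    cells <- keep[cl$membership == cc]
    pool <- cells[interior[cells]]
    if (!length(pool)) pool <- cells
    reps[cc, ] <- G[pool[which.max(depth[pool])], ]
  }
  structure(list(count = cl$no, representatives = reps,
                 resolution = resolution, box = box, stable = NA,
                 membership = cl$membership, cells = keep),
            class = "grid_labeling")
}

slice_idx <- function(idx, ax, range) {
  args <- rep(list(quote(expr = )), length(dim(idx)))
  args[[ax]] <- range
  do.call(`[`, c(list(idx), args))
}

#' @export
print.grid_labeling <- function(x, ...) {
  cat("grid labeling:", x$count, "components at resolution", x$resolution,
      if (isTRUE(x$stable)) "(stabilized)" else if (isFALSE(x$stable)) "(INCONCLUSIVE)"
      else "", "\n")
  invisible(x)
}

qp_is_homogeneous <- function(p) {
  nrow(p$E) > 0 && length(unique(rowSums(p$E))) == 1
}

#' Roadmap component count of an arrangement complement (positive orthant)
#'
#' Samples the positive orthant (or, when every arrangement polynomial is
#' homogeneous, the unit simplex: positive scaling then gives a bijection of
#' regions), joins each sample to its nearest neighbours *within the same
#' sign-vector class* whenever the connecting segment keeps a constant sign
#' vector, and counts graph components. Robust in the thin-wedge regime
#' where fixed-resolution grids fragment.
#'
#' @param arr a [hypersurface_arrangement()].
#' @param n number of samples.
#' @param seed sampling seed.
#' @param knn neighbours per sample (within its sign class).
#' @param subdivisions points checked along each segment.
#' @param box sampling box upper bound per axis (ignored for homogeneous
#'   arrangements, which use the simplex).
#' @return list with `count`, `representatives`, `homogeneous`, `membership`.
#' @export
roadmap_components <- function(arr, n = 20000, seed = 1L, knn = 12,
                               subdivisions = 120, box = 3) {
  k <- length(arr$parameters)
  homo <- all(vapply(arr$polys, qp_is_homogeneous, TRUE))
  set.seed(seed)
  P <- matrix(stats::rexp(n * k), n, k)
  if (homo) P <- P / rowSums(P) else {
    P <- matrix(stats::runif(n * k), n, k) * box
  }
  colnames(P) <- arr$parameters
  V <- arr_eval(arr, P)
  if (is.null(dim(V))) V <- matrix(V, n)
  S <- sign(V)
  okr <- rowSums(S == 0) == 0
  P <- P[okr, , drop = FALSE]; S <- S[okr, , drop = FALSE]
  code <- sign_code(S)
  from <- to <- integer(0)
  for (cd in unique(code)) {
    cls <- which(code == cd)
    if (length(cls) < 2) next
    kk <- min(knn, length(cls) - 1)
    DM <- as.matrix(stats::dist(P[cls, , drop = FALSE]))
    for (ii in seq_along(cls)) {
      nb <- order(DM[ii, ])[2:(kk + 1)]
      from <- c(from, rep(cls[ii], length(nb)))
      to <- c(to, cls[nb])
    }
  }
  keepseg <- segment_constant_sign(arr, P, from, to, S, subdivisions)
  g <- igraph::make_graph(edges = c(rbind(from[keepseg], to[keepseg])),
                          n = nrow(P), directed = FALSE)
  cl <- igraph::components(g)
  # healing pass: small components retry with a larger neighbourhood
  small <- which(tabulate(cl$membership, cl$no) <= 4)
  if (length(small)) {
    f2 <- t2 <- integer(0)
    for (sc in small) {
      pts <- which(cl$membership == sc)
      for (pi in pts) {
        cls <- which(code == code[pi] & cl$membership != sc)
        if (!length(cls)) next
        d <- sqrt(colSums((t(P[cls, , drop = FALSE]) - P[pi, ])^2))
        nb <- cls[order(d)[seq_len(min(60, length(cls)))]]
        ks <- segment_constant_sign(arr, P, rep(pi, length(nb)), nb, S, 4 * subdivisions)
        f2 <- c(f2, rep(pi, sum(ks))); t2 <- c(t2, nb[ks])
      }
    }
    if (length(f2)) {
      g <- igraph::add_edges(g, c(rbind(f2, t2)))
      cl <- igraph::components(g)
    }
  }
  depth <- if (ncol(V)) apply(sweep(abs(V[okr, , drop = FALSE]), 2,
                                    colMeans(abs(V)) + 1e-300, "/"), 1, min)
           else rep(1, nrow(P))
  reps <- matrix(NA_real_, cl$no, k, dimnames = list(NULL, arr$parameters))
  for (cc in seq_len(cl$no)) {
    pts <- which(cl$membership == cc)
    reps[cc, ] <- P[pts[which.max(depth[pts])], ]
  }
  list(count = cl$no, representatives = reps, homogeneous = homo,
       membership = cl$membership, points = P)
}

segment_constant_sign <- function(arr, P, from, to, S, subdivisions) {
  if (!length(from)) return(logical(0))
  keep <- rep(TRUE, length(from))
  tseq <- seq(0, 1, length.out = subdivisions)[-c(1, subdivisions)]
  chunk <- max(1, floor(200000 / subdivisions))
  for (s0 in seq(1, length(from), by = chunk)) {
    e0 <- min(s0 + chunk - 1, length(from))
    ii <- from[s0:e0]; jj <- to[s0:e0]
    m <- length(ii)
    Aseg <- P[rep(ii, each = length(tseq)), , drop = FALSE] +
      (P[rep(jj, each = length(tseq)), , drop = FALSE] -
       P[rep(ii, each = length(tseq)), , drop = FALSE]) * tseq
    SV <- sign(arr_eval(arr, Aseg))
    if (is.null(dim(SV))) SV <- matrix(SV, nrow(Aseg))
    ref <- S[rep(ii, each = length(tseq)), , drop = FALSE]
    okseg <- rowSums(SV != ref) == 0
    keep[s0:e0] <- vapply(seq_len(m), function(q)
      all(okseg[((q - 1) * length(tseq) + 1):(q * length(tseq))]), TRUE)
  }
  keep
}

#' Random line/conic arrangements for property tests
#'
#' Draws `m` random hypersurfaces (lines and/or axis-aligned ellipses with
#' small rational coefficients) in `k` dimensions, rejection-sampled so that
#' no two factors coincide and every factor is nonsingular.
#'
#' @param k dimension (1 or 2).
#' @param m number of hypersurfaces (<= 4).
#' @param degree_menu degrees to draw from (subset of `c(1, 2)`).
#' @param seed sampling seed.
#' @param box placement box upper bound.
#' @return a [hypersurface_arrangement()].
#' @export
random_arrangement <- function(k, m, degree_menu = c(1, 2), seed = 1L, box = 10) {
  stopifnot(k %in% 1:2, m <= 4, all(degree_menu %in% 1:2))
  set.seed(seed)
  pars <- paste0("a", seq_len(k))
  polys <- list(); descs <- list()
  budget <- 400
  while (length(polys) < m && budget > 0) {
    budget <- budget - 1
    deg <- sample(rep(degree_menu, 2), 1)
    if (deg == 1 || k == 1) {
      cf <- sample(-6:6, k, replace = TRUE)
      if (all(cf == 0)) next
      q <- qp_const(pars, rat(-sample(1:(2 * box), 1), 2))
      for (j in seq_len(k))
        q <- qp_add(q, qp_scale(qp_var(pars, pars[j]), rat(cf[j])))
      d <- list(type = "line", cf = cf)
    } else {
      ctr <- sample(3:(box - 1), k, replace = TRUE)
      ax <- sample(1:4, k, replace = TRUE)
      rad <- sample(2:9, 1)
      # keep the whole ellipse well inside (0.5, box + 2): the counting box
      # must contain every region pinch, or in-box and whole-quadrant
      # region counts can differ
      ext <- sqrt(rad / ax)
      if (any(ctr - ext < 0.5) || any(ctr + ext > box + 2)) next
      q <- qp_const(pars, rat(-rad))
      for (j in seq_len(k)) {
        dj <- qp_sub(qp_var(pars, pars[j]), qp_const(pars, rat(ctr[j])))
        q <- qp_add(q, qp_scale(qp_mul(dj, dj), rat(ax[j])))
      }
      d <- list(type = "ellipse", ctr = ctr, ax = ax, rad = rad)
    }
    p <- qp_normalize(q)
    if (any(vapply(polys, function(o) qp_proportional(o, p), TRUE))) next
    # transversality rejection: near-tangent pairs create sliver regions on
    # which no counting oracle is reliable
    ok <- TRUE
    for (i in seq_along(polys)) {
      if (!pair_transversal(descs[[i]], d, polys[[i]], p)) { ok <- FALSE; break }
    }
    if (!ok) next
    polys <- c(polys, list(p)); descs <- c(descs, list(d))
  }
  if (length(polys) < m) stop("rejection budget exhausted", call. = FALSE)
  hypersurface_arrangement(polys, pars, normalized = TRUE)
}

# do two curves (lines / axis-aligned ellipses in the plane) either miss
# each other cleanly or cross transversally?
pair_transversal <- function(d1, d2, p1, p2, min_sin = 0.2) {
  if (d1$type == "line" && d2$type == "line") {
    n1 <- d1$cf / sqrt(sum(d1$cf^2)); n2 <- d2$cf / sqrt(sum(d2$cf^2))
    return(abs(n1[1] * n2[2] - n1[2] * n2[1]) > min_sin)
  }
  # put an ellipse first and walk along it
  if (d1$type != "ellipse") { tmp <- d1; d1 <- d2; d2 <- tmp; tp <- p1; p1 <- p2; p2 <- tp }
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  P <- cbind(d1$ctr[1] + sqrt(d1$rad / d1$ax[1]) * cos(th),
             d1$ctr[2] + sqrt(d1$rad / d1$ax[2]) * sin(th))
  colnames(P) <- p1$vars
  v <- qp_eval(p2, P)
  scale2 <- stats::median(abs(v)) + 1e-12
  flips <- which(diff(sign(v)) != 0)
  # near-touch without a crossing
  if (!length(flips) && min(abs(v)) / scale2 < 0.02) return(FALSE)
  for (f in flips) {
    x <- P[f, ]
    g1 <- c(2 * d1$ax[1] * (x[1] - d1$ctr[1]), 2 * d1$ax[2] * (x[2] - d1$ctr[2]))
    g2 <- if (d2$type == "line") d2$cf else
      c(2 * d2$ax[1] * (x[1] - d2$ctr[1]), 2 * d2$ax[2] * (x[2] - d2$ctr[2]))
    g1 <- g1 / sqrt(sum(g1^2)); g2 <- g2 / sqrt(sum(g2^2))
    if (abs(g1[1] * g2[2] - g1[2] * g2[1]) < min_sin) return(FALSE)
  }
  TRUE
}
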