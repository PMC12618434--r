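# Gradient-flow connectivity: trace trajectories of
# sign(r_c) * grad r_c from the unstable directions of higher-index routing
# points, build the routing graph, and answer membership queries. Each
# connected component of the graph corresponds to one connected component
# of the arrangement complement.

# monotone gradient ascent on |r|: adaptive step with backtracking, so the
# trajectory can never cross the boundary (where r = 0). Returns the final
# point and the |r| trace.
# batched value+gradient of r at the rows of X
rf_val_grad_batch <- function(rf, X) {
  ne <- rf_num_eval(rf, X, hessian = FALSE)
  dd <- rf_den(rf, X)
  amc <- sweep(X, 2, rf$center_num)
  list(r = ne$val / dd^rf$D,
       g = (dd * ne$grad - 2 * rf$D * ne$val * amc) / dd^(rf$D + 1))
}

# monotone gradient ascent on |r| for many trajectories in lockstep; the
# per-step evaluations are vectorized over the active rows
ascend_batch <- function(rf, X0, gtol = 1e-7, max_steps = 5000, escape = 1e6) {
  X <- as.matrix(X0)
  n <- nrow(X)
  vg <- rf_val_grad_batch(rf, X)
  s <- sign(vg$r)
  v <- abs(vg$r)
  g <- s * vg$g
  nx <- 1 + sqrt(rowSums(X^2))
  gn <- sqrt(rowSums(g^2))
  h <- 0.1 * nx / (gn + 1e-300)
  ok <- s != 0
  active <- ok
  for (step in seq_len(max_steps)) {
    gn <- sqrt(rowSums(g^2))
    nx <- 1 + sqrt(rowSums(X^2))
    active <- active & (gn * nx >= gtol * v) & (nx - 1 < escape)
    idx <- which(active)
    if (!length(idx)) break
    h[idx] <- pmin(h[idx], 0.25 * nx[idx] / gn[idx])
    Xn <- X[idx, , drop = FALSE] + h[idx] * g[idx, , drop = FALSE]
    Xm <- X[idx, , drop = FALSE] + 0.5 * h[idx] * g[idx, , drop = FALSE]
    rr <- rf_value(rf, rbind(Xn, Xm))
    rn <- rr[seq_along(idx)]; rm <- rr[length(idx) + seq_along(idx)]
    acc <- is.finite(rn) & is.finite(rm) & sign(rn) == s[idx] &
      sign(rm) == s[idx] & abs(rn) > v[idx] & abs(rm) >= v[idx] * (1 - 1e-12)
    ia <- idx[acc]
    if (length(ia)) {
      X[ia, ] <- Xn[acc, , drop = FALSE]
      v[ia] <- abs(rn[acc])
      vg2 <- rf_val_grad_batch(rf, X[ia, , drop = FALSE])
      g[ia, ] <- s[ia] * vg2$g
      h[ia] <- h[ia] * 1.3
    }
    ir <- idx[!acc]
    if (length(ir)) {
      h[ir] <- h[ir] / 2
      active[ir[h[ir] < 1e-15 * (1 + sqrt(rowSums(X[ir, , drop = FALSE]^2)))]] <- FALSE
    }
  }
  list(X = X, value = s * v, started = ok)
}

rf_val_grad <- function(rf, x) {
  A <- matrix(x, 1)
  ne <- rf_num_eval(rf, A, hessian = FALSE)
  dd <- rf_den(rf, A)
  amc <- x - rf$center_num
  list(r = ne$val / dd^rf$D,
       g = (dd * ne$grad[1, ] - 2 * rf$D * ne$val * amc) / dd^(rf$D + 1))
}

ascend <- function(rf, x0, gtol = 1e-7, max_steps = 5000, escape = 1e6) {
  x <- x0
  vg <- rf_val_grad(rf, x)
  s <- sign(vg$r)
  if (s == 0) stop("ascent started on the boundary", call. = FALSE)
  v <- abs(vg$r)
  g <- s * vg$g
  h <- 0.1 * (1 + sqrt(sum(x^2))) / (sqrt(sum(g^2)) + 1e-300)
  steps <- 0
  repeat {
    steps <- steps + 1
    if (steps > max_steps) break
    gn <- sqrt(sum(g^2))
    # scale-invariant stationarity: |grad r| (1+|x|) relative to |r|, so the
    # criterion is unaffected by constant rescalings of r
    if (gn * (1 + sqrt(sum(x^2))) < gtol * v) break
    # cap the displacement so a single step cannot hop across a boundary
    # valley into a different region
    hmax <- 0.25 * (1 + sqrt(sum(x^2))) / gn
    h <- min(h, hmax)
    xn <- x + h * g
    # endpoint and midpoint in one batched evaluation
    rr <- rf_value(rf, rbind(xn, x + 0.5 * h * g))
    rn <- rr[1]; rm <- rr[2]
    accept <- is.finite(rn) && is.finite(rm) &&
      sign(rn) == s && sign(rm) == s &&
      abs(rn) > v && abs(rm) >= v * (1 - 1e-12)
    if (accept) {
      x <- xn; v <- abs(rn)
      g <- s * rf_val_grad(rf, x)$g
      h <- h * 1.25
    } else {
      h <- h / 2
      if (h < 1e-15 * (1 + sqrt(sum(x^2)))) break
    }
    if (sqrt(sum(x^2)) > escape)
      stop("gradient trajectory escaped (norm > ", escape, ")", call. = FALSE)
  }
  list(x = x, value = s * v, steps = steps)
}

match_vertex <- function(points, x, tol = 1e-5) {
  if (!length(points)) return(NA_integer_)
  d <- vapply(points, function(p) sqrt(sum((p$coords - x)^2)), 0)
  rel <- d / (1 + vapply(points, function(p) sqrt(sum(p$coords^2)), 0))
  i <- which.min(rel)
  if (rel[i] > tol) return(NA_integer_)
  o <- sort(rel)
  if (length(o) > 1 && o[2] < 2 * o[1] && o[2] < tol)
    stop("ambiguous landing: two routing points within matching tolerance",
         call. = FALSE)
  i
}

# settle an ascent endpoint onto a routing point: Newton-polish the cleared
# gradient system, then match against the vertex list
settle <- function(rf, points, x, tol = 1e-5) {
  i <- match_vertex(points, x, tol)
  if (!is.na(i)) return(i)
  pol <- rf_newton(rf, matrix(x, 1), iters = 30, clip = 0.25)
  if (all(is.finite(pol))) {
    i <- match_vertex(points, pol[1, ], tol)
    if (!is.na(i)) return(i)
  }
  NA_integer_
}

launch_point <- function(rf, point, direction, eps = 1e-4) {
  v0 <- abs(point$value)
  for (try in 1:10) {
    x0 <- point$coords + eps * (1 + sqrt(sum(point$coords^2))) * direction
    r0 <- rf_value(rf, x0)
    if (abs(r0) > v0 * (1 - 1e-12) && sign(r0) == sign(point$value))
      return(x0)
    eps <- eps / 2
  }
  stop("could not launch from routing point: |r| decreases in the unstable direction",
       call. = FALSE)
}

#' Trace a gradient-flow path from an unstable direction of a routing point
#'
#' Starting a small offset from a routing point of index > 0 along an
#' unstable eigenvector direction, follows the flow
#' \eqn{\dot y = \mathrm{sign}(r_c)\,\nabla r_c(y)} (implemented as monotone
#' adaptive ascent on \eqn{|r_c|}, which therefore cannot cross the
#' boundary) until the gradient vanishes, and returns the routing point at
#' which the trajectory lands -- by construction in the same connected
#' component.
#'
#' @param rf a `routing_function`.
#' @param point a `routing_point` with `index > 0`.
#' @param direction unit vector: an unstable eigenvector direction (either
#'   sign).
#' @param points list of all routing points (for landing identification).
#' @param eps launch offset scale.
#' @return index (into `points`) of the landing routing point, with
#'   attribute `path_values` (the monotone |r| record endpoints).
#' @export
trace_unstable_path <- function(rf, point, direction, points, eps = 1e-4) {
  stopifnot(point$index > 0)
  v0 <- abs(point$value)
  x0 <- launch_point(rf, point, direction, eps)
  res <- ascend(rf, x0)
  land <- settle(rf, points, res$x)
  if (is.na(land)) {
    # the flow can discover a routing point the solver missed (e.g. outside
    # its search box); polish and validate it, and report it as new
    pol <- rf_newton(rf, matrix(res$x, 1), iters = 40, clip = 1)
    acc <- rf_accept(rf, pol, pos_tol = if (rf$restrict_positive) 1e-9 else -Inf)
    if (nrow(acc) != 1)
      stop("trajectory from routing point (",
           paste(signif(point$coords, 6), collapse = ", "),
           ") did not land at a known routing point", call. = FALSE)
    newp <- classify(rf, acc[1, ])
    if (abs(newp$value) < v0 * (1 - 1e-9))
      stop("landing value |r| smaller than at the saddle: tracing failed",
           call. = FALSE)
    return(structure(NA_integer_, new_point = newp,
                     path_values = c(point$value, res$value)))
  }
  if (abs(points[[land]]$value) < v0 * (1 - 1e-9))
    stop("landing value |r| smaller than at the saddle: tracing failed",
         call. = FALSE)
  structure(land, path_values = c(point$value, res$value))
}

#' Build the routing graph (connected-components algorithm)
#'
#' Loops over all routing points and all unstable eigenvector directions
#' (\eqn{\pm v} per unstable eigenvector), traces each gradient path and
#' records an edge to the landing point. The connected components of the
#' resulting graph are in one-to-one correspondence with the connected
#' components of the arrangement complement.
#'
#' @param rf a `routing_function`.
#' @param points list of `routing_point`s (classified, genericity-checked).
#' @return object of class `routing_graph` with `vertices`, `edges`
#'   (data.frame from/to/direction) and `components` (vertex partition).
#' @export
build_routing_graph <- function(rf, points) {
  parent <- seq_along(points)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- NULL
  queue <- seq_along(points)
  while (length(queue)) {
    # collect every pending launch (vertex x unstable direction x sign) and
    # trace all trajectories in one batched ascent
    launches <- NULL
    for (i in queue) {
      p <- points[[i]]
      if (p$index == 0) next
      for (d in seq_along(p$unstable_dirs)) {
        for (sgn in c(1, -1)) {
          x0 <- launch_point(rf, p, sgn * p$unstable_dirs[[d]])
          launches <- rbind(launches,
                            cbind(matrix(x0, 1), from = i, dir = d, sgn = sgn))
        }
      }
    }
    queue <- integer(0)
    if (is.null(launches)) break
    k <- rf$k
    res <- ascend_batch(rf, launches[, seq_len(k), drop = FALSE])
    for (r in seq_len(nrow(launches))) {
      i <- launches[r, "from"]
      j <- settle(rf, points, res$X[r, ])
      if (is.na(j)) {
        # flow discovered a routing point the solver missed: append it
        pol <- rf_newton(rf, res$X[r, , drop = FALSE], iters = 40, clip = 1)
        acc <- rf_accept(rf, pol, pos_tol = if (rf$restrict_positive) 1e-9 else -Inf)
        if (nrow(acc) != 1)
          stop("trajectory from routing point (",
               paste(signif(points[[i]]$coords, 6), collapse = ", "),
               ") did not land at a known routing point", call. = FALSE)
        points[[length(points) + 1]] <- classify(rf, acc[1, ])
        j <- length(points)
        parent[j] <- j
        queue <- c(queue, j)
      }
      if (abs(points[[j]]$value) < abs(points[[i]]$value) * (1 - 1e-9))
        stop("landing value |r| smaller than at the saddle: tracing failed",
             call. = FALSE)
      edges <- rbind(edges, data.frame(from = i, to = as.integer(j),
                                       eigendir = launches[r, "dir"],
                                       sign = launches[r, "sgn"]))
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  nv <- length(points)
  comp_id <- vapply(seq_len(nv), find, 0)
  # segment witnesses: a constant-factor-sign path between two routing
  # points proves they share a region even when the connecting saddle lies
  # beyond the solver's reach (e.g. far out in an unbounded region)
  comp_id <- witness_merge(rf, points, comp_id)
  comp_id <- match(comp_id, unique(comp_id))
  structure(list(vertices = points, edges = edges, component_id = comp_id,
                 rf = rf),
            class = "routing_graph")
}

rf_sign_matrix <- function(rf, A) {
  S <- vapply(rf$fcache, function(f) sign(np_eval(f$val, A)), numeric(nrow(A)))
  if (is.null(dim(S))) S <- matrix(S, nrow(A))
  S
}

# merge components of the routing graph that are provably connected by a
# polyline of constant-sign segments through auxiliary sample points
witness_merge <- function(rf, points, comp_id, n_aux = NULL, subdivisions = 400) {
  if (length(unique(comp_id)) < 2) return(comp_id)
  k <- rf$k
  if (is.null(n_aux)) n_aux <- 150 * k
  V <- do.call(rbind, lapply(points, `[[`, "coords"))
  hi <- 2.5 * max(1, apply(V, 2, max))
  set.seed(rf$seed + 777L)
  aux <- matrix(stats::runif(n_aux * k, 1e-3, hi), n_aux, k)
  P <- rbind(V, aux)
  S <- rf_sign_matrix(rf, P)
  ok <- rowSums(S == 0) == 0
  code <- apply(S, 1, paste, collapse = ",")
  # connect same-code nearest neighbours whose joining segment never
  # changes any factor sign
  parent <- seq_len(nrow(P))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  tseq <- seq(0, 1, length.out = subdivisions)[-c(1, subdivisions)]
  for (cd in unique(code[ok])) {
    cls <- which(ok & code == cd)
    if (length(cls) < 2) next
    DM <- as.matrix(stats::dist(P[cls, , drop = FALSE]))
    kk <- min(10, length(cls) - 1)
    for (ii in seq_along(cls)) {
      for (jj in order(DM[ii, ])[2:(kk + 1)]) {
        a <- P[cls[ii], ]; b <- P[cls[jj], ]
        if (find(cls[ii]) == find(cls[jj])) next
        seg <- outer(1 - tseq, a) + outer(tseq, b)
        Sv <- rf_sign_matrix(rf, seg)
        if (all(sweep(Sv, 2, S[cls[ii], ], `==`))) {
          parent[find(cls[ii])] <- find(cls[jj])
        }
      }
    }
  }
  root <- vapply(seq_len(nrow(P)), find, 0)
  out <- comp_id
  nvert <- length(points)
  for (i in seq_len(nvert)) for (j in seq_len(nvert)) {
    if (i < j && root[i] == root[j] && out[i] != out[j])
      out[out == out[j]] <- out[i]
  }
  out
}

#' @export
print.routing_graph <- function(x, ...) {
  cat("routing graph:", length(x$vertices), "vertices,",
      if (is.null(x$edges)) 0 else nrow(x$edges), "edges,",
      length(unique(x$component_id)), "connected components\n")
  invisible(x)
}

#' Connected components of a routing graph
#'
#' @param graph a `routing_graph`.
#' @return list of components, each with `vertices` (indices),
#'   `representative` (index of the index-0 vertex of largest |r|) and
#'   `representative_coords`.
#' @export
connected_components <- function(graph) {
  ids <- sort(unique(graph$component_id))
  lapply(ids, function(cid) {
    vs <- which(graph$component_id == cid)
    idx0 <- vs[vapply(graph$vertices[vs], function(p) p$index == 0, TRUE)]
    if (!length(idx0))
      stop("integrity error: component without an index-0 routing point",
           call. = FALSE)
    rep_v <- idx0[which.max(vapply(graph$vertices[idx0],
                                   function(p) abs(p$value), 0))]
    list(id = cid, vertices = vs, representative = rep_v,
         representative_coords = graph$vertices[[rep_v]]$coords)
  })
}

#' Locate the region containing a parameter point
#'
#' Follows the gradient flow \eqn{\dot y = \mathrm{sign}(r_c(a)) \nabla
#' r_c(y)} from `a` until it lands at a routing point, and returns that
#' point's connected-component id. The query point must be off the boundary.
#'
#' @param rf a `routing_function`.
#' @param graph the `routing_graph` of `rf`.
#' @param a query point (numeric vector).
#' @param boundary_tol relative tolerance below which `a` is rejected as
#'   (numerically) on the boundary.
#' @return component id (integer), with attribute `vertex` (landing vertex).
#' @export
locate <- function(rf, graph, a, boundary_tol = 1e-9) {
  A <- matrix(a, 1)
  nr <- 1 + sqrt(sum(a^2))
  rel <- vapply(rf$fcache, function(f) {
    fv <- abs(np_eval(f$val, A))
    gn <- sqrt(sum(vapply(f$grad, function(g)
      if (nrow(g$E)) np_eval(g, A)^2 else 0, 0)))
    fv / ((gn + fv / nr + 1e-300) * nr)
  }, 0)
  if (min(rel) < boundary_tol)
    stop("query point is on/near the boundary (relative factor distance ",
         format(min(rel), digits = 3), ")", call. = FALSE)
  i <- match_vertex(graph$vertices, a, tol = 1e-7)
  if (is.na(i)) {
    res <- ascend(rf, a)
    i <- settle(rf, graph$vertices, res$x)
  }
  if (is.na(i))
    stop("gradient flow from query point did not land at a routing point",
         call. = FALSE)
  structure(graph$component_id[i], vertex = i)
}
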