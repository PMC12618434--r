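# Stability-landscape labeling: classify each connected region of parameter
# space by its set of stable steady-state types, produce two-parameter
# landscape slices, and collect trajectory evidence for regions with an
# empty stable set (candidate limit cycles).

# display vocabulary for stable-state sets over the standard coral labels
STABLE_SET_NAMES <- list(
  "E_0"       = "Total extinction",
  "E_x"       = "Coral only",
  "E_xy"      = "Mutualist exclusion",
  "E_xz"      = "Pathogen exclusion",
  "E_co"      = "Coexistence",
  "E_0+E_xy"  = "Extinction or mutualist exclusion",
  "E_0+E_xz"  = "Extinction or pathogen exclusion",
  "E_0+E_co"  = "Extinction or coexistence",
  "E_x+E_xz"  = "Coral only or pathogen exclusion",
  "E_x+E_xy"  = "Coral only or mutualist exclusion",
  "E_co+E_x"  = "Coral only or coexistence"
)

STABLE_SET_COLORS <- c(
  "E_0" = "#777777", "E_x" = "#ffd92f", "E_xy" = "#fc8d62", "E_xz" = "#8da0cb",
  "E_co" = "#66c2a5", "empty" = "#ffffff"
)

#' Label a set of stable equilibrium types
#'
#' @param labels character vector of equilibrium-type labels (e.g.
#'   `c("E_x", "E_co")`); may be empty.
#' @return object of class `stable_state_set`: list with `labels` (sorted),
#'   `key` (canonical serialization), `display` name and `color`.
#' @export
stable_state_set <- function(labels) {
  labels <- sort(unique(as.character(labels)))
  key <- if (length(labels)) paste(labels, collapse = "+") else "empty"
  display <- if (key == "empty") "No stable steady state (limit cycle possible)"
             else STABLE_SET_NAMES[[key]] %||%
                  paste(vapply(labels, function(l) STABLE_SET_NAMES[[l]] %||% l, ""),
                        collapse = " or ")
  color <- if (key %in% names(STABLE_SET_COLORS)) STABLE_SET_COLORS[[key]]
           else if (length(labels) == 1) STABLE_SET_COLORS[["empty"]]
           else STABLE_SET_COLORS[[labels[1]]] %||% "#cccccc"
  structure(list(labels = labels, key = key, display = display, color = color),
            class = "stable_state_set")
}

#' Parse a stable-state-set key back into the set
#' @param key canonical key such as `"E_x+E_co"` or `"empty"`.
#' @return a [stable_state_set()].
#' @export
parse_stable_state_set <- function(key) {
  stable_state_set(if (identical(key, "empty")) character(0)
                   else strsplit(key, "+", fixed = TRUE)[[1]])
}

#' @export
print.stable_state_set <- function(x, ...) {
  cat(x$key, "--", x$display, "\n")
  invisible(x)
}

#' Classify the stable steady-state set at a parameter point
#'
#' Solves for all steady states at `a_star`, keeps the real nonnegative
#' ones, assigns each to its equilibrium type by its pattern of zero
#' coordinates, tests stability by the Routh polynomials, and returns the
#' set of types carrying a stable representative.
#'
#' @param sys an [ode_system].
#' @param a_star named parameter values (strictly inside a region).
#' @param zero_tol coordinates below this are treated as exactly zero.
#' @param near_tol coordinates (or Routh values) within `(zero_tol,
#'   near_tol)` of zero flag the region "near-boundary" rather than risking
#'   misclassification.
#' @return list with `stable_set` (a [stable_state_set()]), `n_real_positive`,
#'   `n_real_nonnegative`, `near_boundary`, and a `states` table.
#' @export
classify_region <- function(sys, a_star, zero_tol = 1e-9, near_tol = 1e-6) {
  ss <- steady_states(sys, a_star)
  stable_types <- character(0)
  near <- FALSE
  rows <- list()
  for (i in seq_len(nrow(ss$points))) {
    if (!ss$real[i]) next
    x <- Re(ss$points[i, ])
    if (any(x < -near_tol)) next
    if (any(abs(x) > zero_tol & abs(x) < near_tol)) near <- TRUE
    zero_vars <- sys$variables[abs(x) <= near_tol]
    type <- equilibrium_label(sys$variables, zero_vars)
    verdict <- ss$stability[[i]]
    if (is.null(verdict)) next
    if (identical(as.character(verdict), "boundary")) near <- TRUE
    if (identical(as.character(verdict), "stable")) stable_types <- c(stable_types, type)
    rows[[length(rows) + 1]] <- data.frame(
      type = type, stable = as.character(verdict),
      coords = paste(signif(x, 8), collapse = " "))
  }
  list(stable_set = stable_state_set(stable_types),
       n_real_positive = sum(ss$positive),
       n_real_nonnegative = length(rows),
       near_boundary = near,
       states = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Compute a two-parameter stability-landscape slice
#'
#' Fixes all but two parameters to exact rational values, recomputes the
#' total boundary of the restricted system, runs the full routing pipeline
#' (routing function, critical points, gradient-flow graph) on the
#' two-dimensional arrangement, and classifies the stable steady-state set
#' of every region at its routing-point representative.
#'
#' @param sys an [ode_system] (unfixed parameters must include `free`).
#' @param fixed named list of exact rational values (strings like `"5/2"`)
#'   for the parameters to freeze.
#' @param free character vector of the two parameters spanning the slice.
#' @param window c(lo, hi) plotting/representative window per axis.
#' @param seed routing-center seed.
#' @param classify run steady-state classification per region (needs an ODE
#'   system behind the arrangement).
#' @param timeout per-elimination timeout in seconds.
#' @return object of class `region_report`: a data.frame of regions with the
#'   routing-point representative, steady-state counts, stable-set key and
#'   display name, bistability and empty-set flags; attributes `rf`,
#'   `graph`, `arrangement`, `slice`.
#' @export
landscape_slice <- function(sys, fixed, free, window = c(0, 10), seed = 1L,
                            classify = TRUE, timeout = 600) {
  stopifnot(length(free) == 2)
  sub <- ode_system(sys$variables, sys$parameters_all, sys$rates_text,
                    fixed = c(sys$fixed_text, fixed),
                    name = paste0(sys$name %||% "model", "_slice"))
  if (!identical(sort(sub$parameters), sort(free)))
    stop("after fixing, the free parameters are ",
         paste(sub$parameters, collapse = ", "), " (expected ",
         paste(free, collapse = ", "), ")", call. = FALSE)
  arr <- total_boundary(sub, include_coordinate_hyperplanes = TRUE,
                        timeout = timeout, strategy = "triangular")
  # reorder parameters to the requested axis order
  rp <- routing_points(arr, seed = seed, method = "multistart",
                       box = 1.3 * window[2], restrict_positive = TRUE,
                       grid_assist = TRUE, batches = 6, batch_size = 2000)
  graph <- build_routing_graph(rp$rf, rp$points)
  comps <- connected_components(graph)
  rows <- list()
  for (cmp in comps) {
    rep_pt <- cmp$representative_coords
    names(rep_pt) <- arr$parameters
    in_window <- all(rep_pt >= window[1] & rep_pt <= window[2])
    if (classify) {
      cls <- classify_region(sub, rep_pt)
      key <- cls$stable_set$key
      rows[[length(rows) + 1]] <- data.frame(
        region = cmp$id,
        rep_1 = rep_pt[free[1]], rep_2 = rep_pt[free[2]],
        in_window = in_window,
        n_real_positive = cls$n_real_positive,
        stable_set = key,
        display = cls$stable_set$display,
        bistable = length(cls$stable_set$labels) >= 2,
        empty_stable_set = key == "empty",
        near_boundary = cls$near_boundary)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        region = cmp$id, rep_1 = rep_pt[free[1]], rep_2 = rep_pt[free[2]],
        in_window = in_window, n_real_positive = NA_integer_,
        stable_set = NA_character_, display = NA_character_,
        bistable = NA, empty_stable_set = NA, near_boundary = NA)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("rep_", free)
  rownames(out) <- NULL
  structure(out, class = c("region_report", "data.frame"),
            rf = rp$rf, graph = graph, arrangement = arr,
            slice = list(fixed = fixed, free = free, window = window,
                         seed = seed, system = sub))
}

#' Trajectory evidence for a limit cycle in an empty-stable-set region
#'
#' Integrates the ODE from `x0` at parameters `a_star` and reports
#' boundedness, non-convergence to any steady state, and a recurrence
#' statistic (the minimum return distance of the late trajectory to earlier
#' points). Evidence only -- not a proof of a periodic orbit.
#'
#' @param sys an [ode_system].
#' @param a_star named parameter values.
#' @param x0 initial state (named or in variable order).
#' @param horizon integration time.
#' @param n_steps output resolution.
#' @return list with `bounded`, `converged`, `recurrent`,
#'   `min_state_distance`, `return_distance`, `final_speed`, `trajectory`.
#' @export
detect_limit_cycle_region <- function(sys, a_star, x0, horizon = 500,
                                      n_steps = 2000) {
  avals <- if (is.list(a_star)) vapply(a_star, function(v)
    if (is.character(v)) rat_as_numeric(rat_parse(v)) else as.double(v), 0)
    else a_star
  avals <- avals[sys$parameters]
  deriv <- function(t, y, parms) {
    A <- matrix(c(y, avals), 1,
                dimnames = list(NULL, c(sys$variables, sys$parameters)))
    list(vapply(sys$rates, function(f) qrf_eval(f, A), 0))
  }
  y0 <- if (!is.null(names(x0))) x0[sys$variables] else stats::setNames(x0, sys$variables)
  times <- seq(0, horizon, length.out = n_steps + 1)
  traj <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                       method = "lsoda")
  Y <- traj[, -1, drop = FALSE]
  bounded <- all(is.finite(Y)) && max(abs(Y)) < 1e3
  ss <- steady_states(sys, avals)
  real_pts <- Re(ss$points[ss$real, , drop = FALSE])
  tail_idx <- which(times > 0.8 * horizon)
  min_sd <- if (nrow(real_pts)) min(vapply(tail_idx, function(i)
    min(sqrt(rowSums(sweep(real_pts, 2, Y[i, ])^2))), 0)) else Inf
  final_speed <- sqrt(sum(unlist(deriv(0, Y[nrow(Y), ], NULL))^2))
  converged <- bounded && (min_sd < 1e-4 || final_speed < 1e-8)
  # recurrence: distance from the final point back to the mid trajectory
  mid_idx <- which(times > 0.5 * horizon & times < 0.75 * horizon)
  ret <- if (length(mid_idx)) min(sqrt(rowSums(sweep(Y[mid_idx, , drop = FALSE],
                                                     2, Y[nrow(Y), ])^2))) else Inf
  list(bounded = bounded, converged = converged,
       recurrent = bounded && !converged && ret < 0.5,
       min_state_distance = min_sd, return_distance = ret,
       final_speed = final_speed,
       trajectory = traj)
}
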