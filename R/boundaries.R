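# Boundary computation: decompose the equilibrium ideal into components,
# eliminate state variables from each component together with the Routh
# polynomials and coordinate conditions, and assemble the total boundary as
# a hypersurface arrangement in parameter space.

#' Decompose the equilibrium ideal into components
#'
#' The equilibrium ideal is generated by the cleared-denominator rate
#' polynomials. Components are obtained by recursive factor splitting run to
#' a fixed point: whenever a generator factors (modulo the other generators)
#' as a product, the system branches; inconsistent branches are pruned and
#' branches whose solution set is contained in another's are removed. For
#' per-capita structured ecological models this reproduces the primary
#' decomposition into equilibrium-type families.
#'
#' @param sys an [ode_system].
#' @return list of `component_ideal` objects, each with fields `gens`
#'   (qpoly generators, a Groebner basis), `zero_vars` (variables identically
#'   zero on the component) and `label` (equilibrium-type name such as
#'   `E_0`, `E_x`, `E_xy`, `E_co`).
#' @export
decompose_equilibrium_ideal <- function(sys) {
  syms <- c(sys$variables, sys$parameters)
  res <- cas_one(list(
    op = "decompose",
    polys = lapply(rate_numerators(sys), qp_string, power_op = "**"),
    vars = as.list(sys$variables), pars = as.list(sys$parameters)))
  comps <- lapply(res$components, function(cmp) {
    gens <- lapply(cmp$gens, parse_poly, vars = syms)
    gens <- lapply(gens, qp_align, vars = syms)
    zero_vars <- character(0)
    for (v in sys$variables) {
      vp <- qp_var(syms, v)
      if (any(vapply(gens, function(g) !qp_is_zero(g) && qp_proportional(g, vp), TRUE)))
        zero_vars <- c(zero_vars, v)
    }
    structure(list(gens = gens, zero_vars = zero_vars,
                   label = equilibrium_label(sys$variables, zero_vars),
                   variables = sys$variables, parameters = sys$parameters),
              class = "component_ideal")
  })
  # stable order: by number of zero coordinates (extinction first), then label
  ord <- order(-lengths(lapply(comps, `[[`, "zero_vars")),
               vapply(comps, `[[`, "", "label"))
  comps[ord]
}

equilibrium_label <- function(variables, zero_vars) {
  nz <- setdiff(variables, zero_vars)
  if (length(nz) == 0) "E_0"
  else if (length(nz) == length(variables)) "E_co"
  else paste0("E_", paste(nz, collapse = ""))
}

#' @export
print.component_ideal <- function(x, ...) {
  cat("component", x$label, "\n")
  for (g in x$gens) cat("  ", qp_string(g), "\n")
  invisible(x)
}

# shared elimination call; returns list of normalized qpoly factors with
# attributes zero_ideal / codim_ge_2 / inconsistent
eliminate_component <- function(comp, extra = NULL, timeout = 600, what = "boundary") {
  req <- list(op = "eliminate",
              gens = lapply(comp$gens, qp_string, power_op = "**"),
              vars = as.list(comp$variables), pars = as.list(comp$parameters))
  if (!is.null(extra)) req$extra <- qp_string(extra, power_op = "**")
  res <- tryCatch(cas_one(req, timeout = timeout), error = function(e) {
    stop("elimination failed for component ", comp$label, " (", what, "): ",
         conditionMessage(e), call. = FALSE)
  })
  facs <- lapply(res$factors, function(f) qp_normalize(parse_poly(f, comp$parameters)))
  attr(facs, "zero_ideal") <- isTRUE(res$zero_ideal)
  attr(facs, "codim_ge_2") <- isTRUE(res$codim_ge_2)
  attr(facs, "inconsistent") <- isTRUE(res$inconsistent)
  facs
}

#' Singular boundary of an equilibrium component
#'
#' Parameter values where the component carries a solution with singular
#' Jacobian (vanishing determinant): the classical discriminant locus,
#' computed as the elimination ideal of the component plus
#' \eqn{\det J_x f = 0}.
#'
#' @param comp a `component_ideal` from [decompose_equilibrium_ideal()].
#' @param sys the originating [ode_system].
#' @param timeout seconds allowed for the elimination.
#' @return list of irreducible parameter polynomials (`qpoly`), possibly
#'   empty, with attributes `zero_ideal` and `codim_ge_2`.
#' @export
singular_boundary <- function(comp, sys, timeout = 600) {
  cp <- char_poly_symbolic(sys)
  # c_0 = (-1)^n det(J); same zero set as det
  det_num <- cp$coefficients[[1]]$num
  eliminate_component(comp, det_num, timeout, "singular boundary")
}

char_poly_symbolic <- function(sys) {
  if (is.null(sys$cache$cp)) sys$cache$cp <- char_poly(sys_jacobian_cached(sys))
  sys$cache$cp
}

sys_routh_numerators <- function(sys) {
  if (!is.null(sys$cache$routh_num)) return(sys$cache$routh_num)
  rp <- routh_polynomials(char_poly_symbolic(sys))
  sys$cache$routh_num <- lapply(rp, function(r) r$num)
  sys$cache$routh_num
}

#' Routh-Hurwitz boundary of an equilibrium component
#'
#' Parameter values where some Routh polynomial vanishes at a steady state
#' of the component, i.e. where a stability verdict can change. Processed
#' one Routh polynomial at a time (an easier elimination than the full
#' product) and unioned.
#'
#' @inheritParams singular_boundary
#' @return list of irreducible parameter polynomials (`qpoly`).
#' @export
routh_hurwitz_boundary <- function(comp, sys, timeout = 600) {
  out <- list()
  for (rnum in sys_routh_numerators(sys)) {
    if (qp_is_zero(rnum) || qp_is_const(rnum)) next
    facs <- eliminate_component(comp, rnum, timeout, "Routh-Hurwitz boundary")
    out <- c(out, facs)
  }
  dedupe_factors(out)
}

#' Coordinate boundary of an equilibrium component
#'
#' Parameter values where the component carries a steady state whose named
#' coordinate is zero (a feasibility change). Variables identically zero on
#' the component are skipped; a component whose every parameter value admits
#' such a solution yields the zero-ideal sentinel.
#'
#' @inheritParams singular_boundary
#' @param variable state-variable name.
#' @return list of irreducible parameter polynomials, with attributes
#'   `skipped` and `zero_ideal`.
#' @export
coordinate_boundary <- function(comp, variable, timeout = 600) {
  stopifnot(variable %in% comp$variables)
  if (variable %in% comp$zero_vars) {
    out <- list()
    attr(out, "skipped") <- TRUE
    attr(out, "zero_ideal") <- TRUE
    return(out)
  }
  syms <- c(comp$variables, comp$parameters)
  facs <- eliminate_component(comp, qp_var(syms, variable), timeout,
                              paste0(variable, "-boundary"))
  attr(facs, "skipped") <- FALSE
  facs
}

dedupe_factors <- function(facs) {
  keys <- vapply(facs, function(f) qp_key(qp_normalize(f)), "")
  facs[!duplicated(keys)]
}

#' Total boundary of a parametric ODE system
#'
#' Unions the Routh-Hurwitz and coordinate boundaries over all equilibrium
#' components (the singular boundary is contained in the Routh-Hurwitz
#' boundary since \eqn{c_0 = (-1)^n \det J} is a Routh polynomial), removes
#' redundancies, and returns the result as a hypersurface arrangement in
#' parameter space. With `include_coordinate_hyperplanes`, the parameter
#' coordinate hyperplanes \eqn{a_i = 0} are appended so the arrangement
#' delimits the positive orthant.
#'
#' @param sys an [ode_system].
#' @param include_coordinate_hyperplanes append `a_i = 0` for each parameter.
#' @param timeout seconds allowed per elimination call.
#' @param strategy elimination method: block-order Groebner bases
#'   (`"groebner"`, exact and canonical) or `"triangular"`
#'   (back-substitution of variable-linear generators plus a final
#'   univariate resultant; much faster on slice systems, may introduce
#'   leading-coefficient factors that the deduplication absorbs; falls back
#'   to Groebner when the component does not triangularize).
#' @return a `hypersurface_arrangement`.
#' @export
total_boundary <- function(sys, include_coordinate_hyperplanes = TRUE,
                           timeout = 600,
                           strategy = c("groebner", "triangular")) {
  strategy <- match.arg(strategy)
  comps <- sys_decomposition(sys)
  routh_nums <- Filter(function(p) !qp_is_zero(p) && !qp_is_const(p),
                       sys_routh_numerators(sys))
  # one batched backend call for every (component x target) elimination
  reqs <- list(); tags <- character(0)
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    base <- list(op = "eliminate", strategy = strategy,
                 gens = lapply(comp$gens, qp_string, power_op = "**"),
                 vars = as.list(comp$variables),
                 pars = as.list(comp$parameters))
    for (rn in routh_nums) {
      reqs[[length(reqs) + 1]] <- c(base, list(extra = qp_string(rn, power_op = "**")))
      tags <- c(tags, paste0(comp$label, ":routh"))
    }
    syms <- c(comp$variables, comp$parameters)
    for (v in setdiff(comp$variables, comp$zero_vars)) {
      reqs[[length(reqs) + 1]] <- c(base, list(extra = v))
      tags <- c(tags, paste0(comp$label, ":", v, "-coordinate"))
    }
  }
  res <- cas_batch(reqs, timeout = timeout)
  polys <- list(); prov <- character(0)
  for (i in seq_along(res)) {
    r <- res[[i]]
    if (!is.null(r$error))
      stop("elimination failed (", tags[i], "): ", r$error, call. = FALSE)
    facs <- lapply(r$factors, function(f)
      qp_normalize(parse_poly(f, sys$parameters)))
    polys <- c(polys, facs)
    prov <- c(prov, rep(tags[i], length(facs)))
  }
  keys <- vapply(polys, qp_key, "")
  keep <- !duplicated(keys)
  polys <- polys[keep]; prov <- prov[keep]
  hypersurface_arrangement(polys, sys$parameters,
                           include_coordinates = include_coordinate_hyperplanes,
                           provenance = prov, normalized = TRUE)
}

#' Construct a hypersurface arrangement
#'
#' An arrangement is a list of distinct squarefree irreducible polynomials
#' in the parameters; the stability landscape's regions are the connected
#' components of its complement. User-supplied polynomials are normalized
#' (squarefree irreducible factorization over the rationals, integer
#' coefficients, positive leading coefficient) and deduplicated.
#'
#' @param polynomials list of `qpoly`, or character expressions.
#' @param parameters parameter names (required when expressions are strings).
#' @param include_coordinates also add the coordinate hyperplanes `a_i = 0`.
#' @param provenance optional character tags, one per polynomial.
#' @param normalized set when the inputs are already irreducible/normalized.
#' @return object of class `hypersurface_arrangement` with fields `polys`,
#'   `degrees`, `parameters`, `is_coordinate`, `provenance`.
#' @export
hypersurface_arrangement <- function(polynomials, parameters,
                                     include_coordinates = FALSE,
                                     provenance = NULL, normalized = FALSE) {
  if (length(polynomials) && is.character(polynomials[[1]]))
    polynomials <- lapply(polynomials, parse_poly, vars = parameters)
  polynomials <- lapply(polynomials, qp_align, vars = parameters)
  if (!normalized && length(polynomials)) {
    out <- list()
    for (p in polynomials) out <- c(out, cas_factor(p))
    polynomials <- lapply(out, qp_normalize)
    provenance <- NULL
  }
  if (is.null(provenance)) provenance <- rep("input", length(polynomials))
  nonconst <- vapply(polynomials, function(p) !qp_is_const(p), TRUE)
  polynomials <- polynomials[nonconst]; provenance <- provenance[nonconst]
  keys <- vapply(polynomials, function(p) qp_key(qp_normalize(p)), "")
  keep <- !duplicated(keys)
  polynomials <- polynomials[keep]; provenance <- provenance[keep]
  is_coord <- vapply(polynomials, function(p) {
    nrow(p$E) == 1 && sum(p$E) == 1
  }, TRUE)
  if (include_coordinates) {
    have <- vapply(polynomials[is_coord], function(p) p$vars[p$E[1, ] == 1], "")
    for (a in setdiff(parameters, have)) {
      polynomials <- c(polynomials, list(qp_var(parameters, a)))
      provenance <- c(provenance, "coordinate-hyperplane")
      is_coord <- c(is_coord, TRUE)
    }
  }
  structure(list(polys = polynomials,
                 degrees = vapply(polynomials, qp_total_degree, 0),
                 parameters = parameters,
                 is_coordinate = is_coord,
                 provenance = provenance),
            class = "hypersurface_arrangement")
}

#' @export
print.hypersurface_arrangement <- function(x, ...) {
  cat("hypersurface arrangement:", length(x$polys), "hypersurfaces in",
      length(x$parameters), "parameters\n")
  for (i in seq_along(x$polys))
    cat(sprintf("  [deg %d%s] %s\n", x$degrees[i],
                if (x$is_coordinate[i]) ", coord" else "", qp_string(x$polys[[i]])))
  invisible(x)
}

#' @export
length.hypersurface_arrangement <- function(x) length(x$polys)

arr_eval <- function(arr, A) {
  # evaluate all arrangement polynomials at rows of A
  vapply(arr$polys, function(p) qp_eval(p, A), numeric(nrow(A)))
}
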