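# Bridge to the sympy computer-algebra system (Python subprocess).
#
# Standard exact-polynomial steps -- Groebner-basis elimination ideals,
# irreducible factorization over Q, resultants and exact real-root
# isolation -- are delegated to sympy; everything specific to the
# routing-function method lives in R.

the_cas <- new.env(parent = emptyenv())

cas_script <- function() {
  p <- system.file("python", "symbolic.py", package = "stabscape")
  if (p == "") p <- file.path("inst", "python", "symbolic.py")
  if (!file.exists(p)) stop("symbolic.py helper not found", call. = FALSE)
  p
}

#' Is the computer-algebra backend available?
#' @return `TRUE` if `python` with sympy can be executed.
#' @export
cas_available <- function() {
  if (!is.null(the_cas$ok)) return(the_cas$ok)
  ok <- tryCatch({
    out <- suppressWarnings(system2("python", c("-c", shQuote("import sympy")),
                                    stdout = TRUE, stderr = TRUE))
    is.null(attr(out, "status"))
  }, error = function(e) FALSE)
  the_cas$ok <- ok
  ok
}

#' Run a batch of symbolic requests through the sympy helper
#'
#' @param requests list of request lists, each with an `op` field.
#' @param timeout seconds before the subprocess is killed.
#' @return list of response lists; a failed request carries `$error`.
#' @keywords internal
cas_batch <- function(requests, timeout = 600) {
  if (!cas_available())
    stop("python/sympy backend not available", call. = FALSE)
  key <- paste(vapply(requests, function(r) paste(deparse(r), collapse = ""), ""),
               collapse = "\n")
  if (is.null(the_cas$keys)) { the_cas$keys <- list(); the_cas$vals <- list() }
  hit <- which(vapply(the_cas$keys, identical, TRUE, y = key))
  if (length(hit)) return(the_cas$vals[[hit[1]]])
  inp <- tempfile(fileext = ".json"); on.exit(unlink(inp), add = TRUE)
  jsonlite::write_json(requests, inp, auto_unbox = TRUE)
  out <- suppressWarnings(system2("python", cas_script(), stdout = TRUE,
                                  stderr = NULL, stdin = inp, timeout = timeout))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("symbolic backend failed (status ", status,
         if (identical(status, 124L)) ", timeout" else "", ")", call. = FALSE)
  res <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  the_cas$keys[[length(the_cas$keys) + 1]] <- key
  the_cas$vals[[length(the_cas$vals) + 1]] <- res
  res
}

cas_one <- function(req, timeout = 600) {
  res <- cas_batch(list(req), timeout = timeout)[[1]]
  if (!is.null(res$error)) stop("symbolic backend: ", res$error, call. = FALSE)
  res
}

#' Irreducible factors of a polynomial over the rationals
#'
#' @param p a `qpoly` (or expression string).
#' @param vars variable names when `p` is a string.
#' @return list of `qpoly` factors: squarefree, primitive integer
#'   coefficients, positive leading coefficient.
#' @keywords internal
cas_factor <- function(p, vars = NULL) {
  if (inherits(p, "qpoly")) {
    vars <- p$vars
    p <- qp_string(p, power_op = "**")
  }
  res <- cas_one(list(op = "factor", expr = p, syms = as.list(vars)))
  lapply(res$factors, function(f) parse_poly(f, vars))
}
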